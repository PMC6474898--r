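#!/usr/bin/env Rscript
# Stage 1 — simulate every input the analysis consumes.
#
# Two plant samples (low/high light analogues with slopes 0.078 and 0.062),
# a 108-per-category germination table, a 212-trial paired-choice log and an
# 8x8 checkerboard removal assay. All downstream stages read these CSVs.

suppressMessages(library(fadseed))
seed <- 20260926L
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

pop_low <- generate_population(population_gen_params(
  slope = 0.078, regime = "low", seed = seed))
pop_high <- generate_population(population_gen_params(
  slope = 0.062, intercept = 26, regime = "high", seed = seed + 1L))
seeds <- rbind(pop_low$seeds, pop_high$seeds)
plants <- rbind(pop_low$plants, pop_high$plants)
write_fadseed_csv(seeds, file.path(out, "seeds_raw.csv"), "seeds")
write_fadseed_csv(plants, file.path(out, "plants_raw.csv"), "plants")
message(sprintf("simulated %d plants / %d seeds (two light regimes)",
                nrow(plants), nrow(seeds)))

germ <- generate_germination(germination_gen_params(seed = seed + 2L))
write_fadseed_csv(germ, file.path(out, "germination.csv"), "germination")
message(sprintf("simulated germination for %d seeds in %d categories",
                nrow(germ), length(unique(germ$category))))

trials <- generate_trials(trial_gen_params(
  n_trials = 212L, p_unspotted = 0.608, n_sessions = 3L, session_sd = 0.2,
  seed = seed + 3L))
write_fadseed_csv(trials, file.path(out, "trials.csv"), "trials")

grid <- generate_grid(grid_gen_params(side = 8L, preference = 0.75,
                                      seed = seed + 4L))
write_fadseed_csv(grid$layout, file.path(out, "grid_layout.csv"),
                  "grid_layout")
write_fadseed_csv(grid$events[, c("event_index", "time", "row", "col")],
                  file.path(out, "grid_events.csv"), "grid_events")
message(sprintf("simulated %d trials and a %d-cell grid assay",
                nrow(trials), nrow(grid$layout)))
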