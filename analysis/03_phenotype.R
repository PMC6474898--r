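#!/usr/bin/env Rscript
# Stage 3 — plant-level phenotype and seed categorization.
#
# Categorizes seeds into unspotted / mid / spotted within each light regime
# (bottom and top 15% of the spot-cover distribution, rank-based) and
# aggregates to plant level: mean cover, cover variance, mean elaiosome
# area, seed counts.

suppressMessages(library(fadseed))
seeds <- read_fadseed_csv("results/data/seeds_raw.csv")
plants_raw <- read_fadseed_csv("results/data/plants_raw.csv")

seeds$regime <- plants_raw$regime[match(seeds$plant_id, plants_raw$plant_id)]
seeds$category <- NA_character_
for (rg in unique(seeds$regime)) {  # per-regime cut, mirroring the sampling design
  sel <- seeds$regime == rg
  seeds$category[sel] <- categorize_seeds(seeds$spot_cover_pct[sel])
}

plants <- aggregate_plants(seeds)
plants <- merge(plants,
                plants_raw[, c("plant_id", "regime", "n_whorls",
                               "total_flowers")],
                by = "plant_id")

write_fadseed_csv(seeds, "results/seeds.csv", "seeds")
write_fadseed_csv(plants, "results/plants.csv", "plants")
message(sprintf("categorized %d seeds: %s", nrow(seeds),
                paste(sprintf("%d %s", table(seeds$category),
                              names(table(seeds$category))), collapse = ", ")))
message(sprintf("aggregated %d plants; mean cover %.1f%% (range %.1f-%.1f)",
                nrow(plants), mean(plants$mean_cover),
                min(plants$mean_cover), max(plants$mean_cover)))
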