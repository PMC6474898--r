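#!/usr/bin/env Rscript
# Stage 4 — fitness-phenotype association.
#
# Per light regime: OLS of plant mean spot cover on total flowers (the
# fitness proxy), plus the seed-level random-intercept regression of cover
# on seed area, and the regime comparison of cover by rank-sum.

suppressMessages(library(fadseed))
plants <- read_fadseed_csv("results/plants.csv")
seeds <- read_fadseed_csv("results/seeds.csv")

results <- list()
for (rg in unique(plants$regime)) {
  pl <- plants[plants$regime == rg, ]
  fit <- fit_linear(pl$total_flowers, pl$mean_cover)
  results[[paste0("plant_level_", rg)]] <- unclass(fit)
  message(sprintf(
    "%s light: slope %.4f percent/flower (t = %.2f, p = %.2g, R^2 = %.2f, n = %d)",
    rg, fit$slope, fit$t, fit$p_value, fit$r_squared, fit$n))
}

sd_seeds <- seeds[!is.na(seeds$seed_area_px), ]
mixed <- fit_mixed_linear(sd_seeds$spot_cover_pct, sd_seeds$seed_area_px,
                          sd_seeds$plant_id)
results$seed_level_cover_on_area <- unclass(mixed)
message(sprintf(
  "seed-level cover ~ area (plant random intercept): slope %.3g, t = %.2f",
  mixed$slope, mixed$t))

regimes <- split(plants$mean_cover, plants$regime)
if (length(regimes) == 2) {
  cmp <- compare_groups(regimes[[1]], regimes[[2]])
  results$cover_between_regimes <- unclass(cmp)
  message(sprintf("cover between regimes: W = %g, p = %.3g (%s vs %s)",
                  cmp$statistic, cmp$p_value,
                  names(regimes)[1], names(regimes)[2]))
}

jsonlite::write_json(results, "results/fitness_association.json",
                     auto_unbox = TRUE, digits = NA, pretty = TRUE)
message("written: results/fitness_association.json")
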