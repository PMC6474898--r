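#!/usr/bin/env Rscript
# Stage 6 — ant seed-preference assays.
#
# Paired-choice trials: removal fractions, exact sign test, raw odds ratio
# and the mixed-effects logistic model (random intercept per session), on
# both the simulated log and the packaged fixture log whose totals match
# the published 212-trial assay (129 unspotted / 83 spotted removals).
# Grid assay: composition at half removal, removal-order rank test and the
# category-blind hypergeometric null.

suppressMessages(library(fadseed))

analyze_trials <- function(trials, label) {
  pref <- trial_preference(trials)
  mixed <- trial_mixed_logistic(trials, time_col = "session")
  message(sprintf(
    "%s: unspotted removed in %.1f%% of %d trials (sign-test p = %.3g); mixed OR = %.3f (p = %.3g)",
    label, 100 * pref$preference_fraction, sum(pref$removals), pref$p_value,
    mixed$odds_ratio, mixed$p_value))
  list(fraction_unspotted = pref$preference_fraction,
       odds_ratio_raw = pref$odds_ratio, sign_test_p = pref$p_value,
       mixed_odds_ratio = mixed$odds_ratio, mixed_p = mixed$p_value)
}

res <- list()
res$trials_simulated <- analyze_trials(
  read_fadseed_csv("results/data/trials.csv"), "simulated trials")
res$trials_fixture <- analyze_trials(
  read_fadseed_csv(fadseed_example("paired_trials_synthetic.csv")),
  "fixture trials")

grid_sim <- grid_assay(read_fadseed_csv("results/data/grid_layout.csv"),
                       read_fadseed_csv("results/data/grid_events.csv"))
grid_fix <- grid_assay(
  read_fadseed_csv(fadseed_example("grid_layout_synthetic.csv")),
  read_fadseed_csv(fadseed_example("grid_events_synthetic.csv")))

for (nm in c("grid_simulated", "grid_fixture")) {
  g <- if (nm == "grid_simulated") grid_sim else grid_fix
  st <- grid_state(g, 32)
  rt <- grid_rank_test(g)
  tail_p <- random_removal_null(st$removed[["unspotted"]], 32, 32, 64)
  message(sprintf(
    "%s: at half removal %d unspotted / %d spotted remain; rank-test p = %.3g; blind-removal tail p = %.3g",
    nm, st$remaining[["unspotted"]], st$remaining[["spotted"]],
    rt$p_value, tail_p))
  res[[nm]] <- list(removed = as.list(st$removed),
                    remaining = as.list(st$remaining),
                    rank_test_W = unname(rt$statistic),
                    rank_test_p = rt$p_value,
                    hypergeometric_tail_p = tail_p)
}

jsonlite::write_json(res, "results/ant_preference.json", auto_unbox = TRUE,
                     digits = NA, pretty = TRUE)
message("written: results/ant_preference.json")
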