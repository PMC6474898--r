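packaged_grid <- function() {
  grid_assay(read_fadseed_csv(fadseed_example("grid_layout_synthetic.csv")),
             read_fadseed_csv(fadseed_example("grid_events_synthetic.csv")))
}

test_that("trial_preference computes fractions, sign test and raw odds ratio", {
  trials <- read_fadseed_csv(fadseed_example("paired_trials_synthetic.csv"))
  expect_equal(nrow(trials), 212)
  pref <- trial_preference(trials)
  expect_equal(unname(pref$removals), c(129, 83))
  expect_equal(round(100 * pref$preference_fraction, 1), 60.8)
  expect_equal(pref$odds_ratio, 83 / 129)

  even <- tibble::tibble(removed_category = rep(c("unspotted", "spotted"), 10))
  p_even <- trial_preference(even)
  expect_equal(p_even$preference_fraction, 0.5)
  expect_equal(p_even$p_value, 1)

  onesided <- tibble::tibble(removed_category = rep("unspotted", 10))
  p1 <- trial_preference(onesided)
  expect_equal(p1$p_value, 2 * (1 / 2)^10, tolerance = 1e-12)
  expect_error(trial_preference(tibble::tibble(removed_category = character())),
               class = "fadseed_error")
})

test_that("category swap mirrors fraction and odds ratio, preserving p", {
  trials <- generate_trials(trial_gen_params(n_trials = 101, p_unspotted = 0.7,
                                             seed = 2))
  swapped <- dplyr::mutate(trials, removed_category = ifelse(
    removed_category == "unspotted", "spotted", "unspotted"))
  a <- trial_preference(trials)
  b <- trial_preference(swapped)
  expect_equal(b$preference_fraction, 1 - a$preference_fraction)
  expect_equal(b$odds_ratio, 1 / a$odds_ratio)
  expect_equal(b$p_value, a$p_value)
})

test_that("mixed logistic reduces to the raw odds ratio and flags separation", {
  # identical composition in every time point -> zero between-time variance
  trials <- tibble::tibble(
    time = rep(1:10, each = 10),
    removed_category = rep(rep(c("unspotted", "spotted"), c(6, 4)), 10))
  fit <- trial_mixed_logistic(trials)
  raw <- trial_preference(trials)
  expect_lt(abs(fit$odds_ratio - raw$odds_ratio), 1e-3)
  sep <- tibble::tibble(time = rep(1:4, each = 5),
                        removed_category = "unspotted")
  expect_error(trial_mixed_logistic(sep), "separation",
               class = "fadseed_separation")
  expect_error(trial_mixed_logistic(
    tibble::tibble(time = 1, removed_category = c("unspotted", "spotted"))),
    class = "fadseed_error")
})

test_that("mixed logistic recovers a known odds ratio (reduced replicates)", {
  ors <- vapply(1:40, function(i) {
    trials <- generate_trials(trial_gen_params(
      n_trials = 200, p_unspotted = 2 / 3, n_sessions = 20,
      session_sd = 0.5, seed = 3000 + i))
    trial_mixed_logistic(trials, time_col = "session")$odds_ratio
  }, numeric(1))
  # true conditional OR of spotted removal = (1/3)/(2/3) = 0.5
  expect_true(mean(ors) > 0.4 && mean(ors) < 0.62)
})

test_that("grid_state applies the removal log and conserves composition", {
  g <- packaged_grid()
  half <- grid_state(g, 32)
  expect_equal(half$remaining[["unspotted"]], 8)
  expect_equal(half$remaining[["spotted"]], 24)
  none <- grid_state(g, 0)
  expect_equal(unname(none$remaining), c(32L, 32L), ignore_attr = TRUE)
  all_ <- grid_state(g, 64)
  expect_equal(sum(all_$remaining), 0)
  for (k in c(0, 7, 32, 50, 64)) {
    st <- grid_state(g, k)
    expect_equal(st$removed + st$remaining,
                 c(spotted = 32L, unspotted = 32L)[names(st$removed)])
  }
  expect_error(grid_state(g, 65), class = "fadseed_error")
})

test_that("grid_assay validates layout and log integrity", {
  layout <- tibble::tibble(row = c(0, 0, 1, 1), col = c(0, 1, 0, 1),
                           category = c("unspotted", "spotted",
                                        "spotted", "unspotted"))
  events <- tibble::tibble(event_index = 1:2, time = 1:2,
                           row = c(0, 1), col = c(0, 0))
  expect_s3_class(grid_assay(layout, events), "grid_assay")
  bad_layout <- dplyr::mutate(layout, category = "unspotted")
  expect_error(grid_assay(bad_layout, events), "2-coloring",
               class = "fadseed_error")
  bad_cell <- dplyr::mutate(events, row = c(0, 9))
  expect_error(grid_assay(layout, bad_cell), class = "fadseed_data_integrity")
  twice <- tibble::tibble(event_index = 1:2, time = 1:2, row = 0, col = 0)
  expect_error(grid_assay(layout, twice), class = "fadseed_data_integrity")
  out_of_order <- tibble::tibble(event_index = c(2, 1), time = 1:2,
                                 row = c(0, 1), col = c(0, 0))
  expect_error(grid_assay(layout, out_of_order),
               class = "fadseed_data_integrity")
})

test_that("grid_rank_test delegates to the shared rank-sum implementation", {
  g <- packaged_grid()
  gr <- grid_rank_test(g)
  ranks <- seq_len(nrow(g$events))
  direct <- rank_sum_test(ranks[g$events$category == "unspotted"],
                          ranks[g$events$category == "spotted"])
  expect_identical(unclass(gr), unclass(direct))
  # strictly alternating removals: tiny rank shift, far from significance;
  # closed form: |U - E| = n/2 = 16 at 32 + 32, tie-free
  alt_cat <- rep(c("unspotted", "spotted"), 32)
  p_alt <- rank_sum_test(ranks[alt_cat == "unspotted"],
                         ranks[alt_cat == "spotted"])$p_value
  expect_equal(p_alt, 2 * pnorm(-(16 - 0.5) / sqrt(32 * 32 * 65 / 12)),
               tolerance = 1e-12)
  expect_gte(p_alt, 0.5)
  # balanced pairs (u,s,s,u repeated): rank sums coincide exactly, p = 1
  bal_cat <- rep(c("unspotted", "spotted", "spotted", "unspotted"), 16)
  expect_equal(rank_sum_test(ranks[bal_cat == "unspotted"],
                             ranks[bal_cat == "spotted"])$p_value, 1)
  # maximal separation at 32 + 32
  g1 <- generate_grid(grid_gen_params(side = 8, preference = 1, seed = 2))
  expect_lt(grid_rank_test(g1)$p_value, 1e-10)
  g_half <- generate_grid(grid_gen_params(side = 8, preference = 1,
                                          n_removals = 20, seed = 3))
  expect_error(grid_rank_test(g_half), "never removed",
               class = "fadseed_error")
})

test_that("random_removal_null is the hypergeometric tail", {
  expect_equal(random_removal_null(0, 32, 32, 64), 1)
  expect_equal(random_removal_null(33, 64, 32, 64), 0)
  # P(>= 24 unspotted | N = 64, K = 32, k = 32): direct pmf summation
  p_direct <- sum(dhyper(24:32, 32, 32, 32))
  expect_equal(random_removal_null(24, 32, 32, 64), p_direct,
               tolerance = 1e-12)
  # Monte Carlo cross-check within 3 standard errors
  draws <- withr::with_seed(8, rhyper(1e6, 32, 32, 32))
  mc <- mean(draws >= 24)
  se <- sqrt(mc * (1 - mc) / 1e6)
  expect_lt(abs(mc - p_direct), 3 * se + 1e-12)
  expect_error(random_removal_null(5, 70, 32, 64), class = "fadseed_error")
  expect_error(random_removal_null(10, 5, 32, 64), class = "fadseed_error")
})
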