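test_that("inverse KM equals the empirical CDF without censoring", {
  d <- tibble::tibble(category = "x", day = c(1, 2, 3), germinated = TRUE)
  km <- inverse_km(d)
  expect_equal(km$cum_germinated, c(1, 2, 3) / 3)
  # property: random uncensored datasets
  for (i in 1:10) {
    days <- withr::with_seed(i, sample(1:50, 20, replace = TRUE))
    km_i <- inverse_km(tibble::tibble(category = "x", day = days,
                                      germinated = TRUE))
    ecdf_i <- ecdf(days)(km_i$day)
    expect_equal(km_i$cum_germinated, ecdf_i, tolerance = 1e-12)
  }
})

test_that("inverse KM handles censoring via the product-limit formula", {
  # all censored: curve constant at 0
  d0 <- tibble::tibble(category = "x", day = c(5, 6, 7), germinated = FALSE)
  expect_true(all(inverse_km(d0)$cum_germinated == 0))
  # hand-unrolled product limit: events at 2, 5, 8 with censorings at 4, 7
  # S(2) = 4/5, S(5) = 4/5 * 2/3, S(8) = 0
  d <- tibble::tibble(category = "x", day = c(2, 4, 5, 7, 8),
                      germinated = c(TRUE, FALSE, TRUE, FALSE, TRUE))
  km <- inverse_km(d)
  expect_equal(km$cum_germinated[km$day == 2], 1 - 4 / 5)
  expect_equal(km$cum_germinated[km$day == 5], 1 - 4 / 5 * 2 / 3)
  expect_equal(km$cum_germinated[km$day == 8], 1)
  expect_true(all(diff(km$cum_germinated) >= 0))
  expect_true(all(diff(km$at_risk) <= 0))
  expect_error(inverse_km(tibble::tibble(category = character(),
                                         day = numeric(),
                                         germinated = logical())),
               class = "fadseed_error")
})

test_that("rank_sum_test exact mode matches enumeration and closed forms", {
  r <- rank_sum_test(c(1, 2), c(3, 4))
  expect_equal(r$p_value, 1 / 3)          # 2/C(4,2) arrangements as extreme
  expect_equal(unname(r$statistic), 0)
  same <- rank_sum_test(c(1, 2, 3), c(1, 2, 3))
  expect_gte(same$p_value, 0.99)
  # 100 random small instances incl. ties vs the enumeration oracle
  for (i in 1:100) {
    sizes <- withr::with_seed(i, sample(1:5, 2, replace = TRUE) + c(1, 1))
    a <- withr::with_seed(i + 300, sample(1:6, sizes[1], replace = TRUE))
    b <- withr::with_seed(i + 600, sample(1:6, sizes[2], replace = TRUE))
    expect_equal(rank_sum_test(a, b)$p_value, oracle_rank_sum_p(a, b),
                 tolerance = 1e-12)
  }
})

test_that("rank_sum_test agrees with wilcox.test where both are exact", {
  for (i in 1:20) {
    a <- withr::with_seed(i, rnorm(4))
    b <- withr::with_seed(i + 50, rnorm(6))
    expect_equal(rank_sum_test(a, b)$p_value,
                 wilcox.test(a, b, exact = TRUE)$p.value, tolerance = 1e-12)
    expect_equal(unname(rank_sum_test(a, b)$statistic),
                 unname(wilcox.test(a, b)$statistic))
  }
  # large-sample mode agrees with the corrected normal approximation
  a <- withr::with_seed(1, rnorm(30)); b <- withr::with_seed(2, rnorm(30, 0.5))
  expect_equal(rank_sum_test(a, b)$p_value,
               wilcox.test(a, b, exact = FALSE, correct = TRUE)$p.value,
               tolerance = 1e-10)
})

test_that("logrank_test matches a hand-computed O-E table and null cases", {
  same <- tibble::tibble(category = rep(c("a", "b"), each = 4),
                         day = rep(c(1, 2, 3, 4), 2), germinated = TRUE)
  lr0 <- logrank_test(same)
  expect_equal(unname(lr0$statistic), 0, tolerance = 1e-12)
  expect_equal(lr0$p_value, 1)
  # 5 events at day 1 vs 5 at day 10: E_A = 2.5, V = (25/9)(25/100), chisq = 9
  sep <- tibble::tibble(category = rep(c("a", "b"), each = 5),
                        day = rep(c(1, 10), each = 5), germinated = TRUE)
  expect_equal(unname(logrank_test(sep)$statistic), 9, tolerance = 1e-10)
  expect_error(logrank_test(dplyr::mutate(sep, germinated = FALSE)),
               "no events", class = "fadseed_error")
})

test_that("logrank chisq is invariant to increasing day transforms", {
  d <- generate_germination(germination_gen_params(n_per_category = 40,
                                                   seed = 5))
  base <- unname(logrank_test(d)$statistic)
  for (f in list(function(t) 2 * t + 1, sqrt, log1p)) {
    d2 <- dplyr::mutate(d, day = f(day))
    expect_equal(unname(logrank_test(d2)$statistic), base, tolerance = 1e-10)
  }
})

test_that("label permutation of a null dataset gives uniform log-rank p-values", {
  d <- withr::with_seed(11, tibble::tibble(
    category = rep(c("a", "b"), each = 40),
    day = rexp(80, rate = 0.2),
    germinated = runif(80) < 0.85))
  ps <- withr::with_seed(12, vapply(1:2000, function(i) {
    d$category <- sample(d$category)
    logrank_test(d)$p_value
  }, numeric(1)))
  ks <- max(abs(sort(ps) - (seq_along(ps) - 0.5) / length(ps)))
  expect_lt(ks, 0.05)
})

test_that("germination_summary computes per-category fractions", {
  g <- tibble::tibble(category = rep(c("unspotted", "spotted"), c(108, 108)),
                      germinated = c(rep(TRUE, 80), rep(FALSE, 28),
                                     rep(TRUE, 97), rep(FALSE, 11)),
                      day = 5)
  s <- germination_summary(g)
  expect_equal(s$fraction[s$category == "unspotted"], 80 / 108)
  expect_equal(round(100 * s$fraction[s$category == "unspotted"], 1), 74.1)
  g0 <- tibble::tibble(category = "x", germinated = rep(FALSE, 10), day = 1)
  expect_equal(germination_summary(g0)$fraction, 0)
})
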