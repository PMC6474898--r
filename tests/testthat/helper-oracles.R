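# Independent oracles used by the unit and acceptance tests.

# Brute-force two-sided rank-sum p-value by enumerating every assignment of
# the pooled observations to the first group. Recomputes midranks from the
# raw pooled values and works from the rank-sum statistic directly, so it is
# independent of the package's U-statistic code path.
oracle_rank_sum_p <- function(a, b) {
  pooled <- c(a, b)
  n1 <- length(a)
  n <- length(pooled)
  r <- rank(pooled)
  obs <- sum(r[seq_len(n1)])
  mid <- n1 * (n + 1) / 2  # expected rank sum under exchangeability
  picks <- utils::combn(n, n1)
  stats <- apply(picks, 2, function(idx) sum(r[idx]))
  mean(abs(stats - mid) >= abs(obs - mid) - 1e-9)
}

# Closed-form OLS slope/intercept from the 2x2 normal equations.
oracle_ols <- function(x, y) {
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  c(slope = slope, intercept = mean(y) - slope * mean(x))
}

# Direct pixel-count cover from a mask_set, bypassing measure_seed.
oracle_cover_pct <- function(masks) {
  100 * sum(masks$spot) / sum(masks$seed_body)
}

# A tiny deterministic germination table.
small_germination <- function() {
  tibble::tibble(
    seed_id = sprintf("s%02d", 1:10),
    category = rep(c("unspotted", "spotted"), each = 5),
    day = c(2, 4, 5, 7, 8, 1, 1, 2, 3, 9),
    germinated = c(TRUE, FALSE, TRUE, FALSE, TRUE, rep(TRUE, 5)))
}
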