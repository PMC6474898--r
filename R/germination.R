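validate_germination <- function(records) {
  need <- c("category", "day", "germinated")
  if (!all(need %in% names(records))) {
    stop_fadseed(sprintf("germination table needs columns: %s",
                         paste(need, collapse = ", ")),
                 "fadseed_invalid_input")
  }
  if (nrow(records) == 0L) {
    stop_fadseed("germination table is empty", "fadseed_invalid_input")
  }
  if (any(!is.finite(records$day)) || any(records$day <= 0)) {
    stop_fadseed("day must be a positive number (censored rows carry the last observation day)",
                 "fadseed_invalid_input")
  }
  records
}

#' Inverse Kaplan-Meier germination curves per category
#'
#' Product-limit estimator of non-germination, reported as the cumulative
#' germinated proportion 1 - S(t). Non-germinated seeds are right-censored
#' at their last observation day. With no censoring the curve equals the
#' empirical cumulative fraction germinated.
#'
#' @param records Tibble with columns category, day, germinated (logical).
#' @return A tibble of class `km_curves` with columns category, day,
#'   at_risk, n_events, cum_germinated; one row per distinct event/censoring
#'   day per category.
#' @export
inverse_km <- function(records) {
  records <- validate_germination(records)
  cats <- unique(records$category)
  rows <- lapply(cats, function(cat) {
    d <- records[records$category == cat, ]
    if (nrow(d) == 0L) {
      stop_fadseed(sprintf("category '%s' has no records", cat),
                   "fadseed_invalid_input")
    }
    sf <- survival::survfit(
      survival::Surv(d$day, d$germinated) ~ 1, conf.type = "none")
    tibble::tibble(category = cat, day = sf$time, at_risk = sf$n.risk,
                   n_events = sf$n.event, cum_germinated = 1 - sf$surv)
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("km_curves", class(out))
  out
}

#' Plot inverse Kaplan-Meier curves
#'
#' @param curves Output of [inverse_km()].
#' @return A ggplot object (step curves of cumulative germinated proportion
#'   over time, one per category).
#' @export
plot_km <- function(curves) {
  stopifnot(inherits(curves, "km_curves"))
  start <- curves |>
    dplyr::distinct(.data$category) |>
    dplyr::mutate(day = 0, cum_germinated = 0)
  dplyr::bind_rows(start,
                   curves[, c("category", "day", "cum_germinated")]) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$day, y = .data$cum_germinated,
                                 colour = .data$category)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "day", y = "cumulative proportion germinated",
                  colour = "seed category") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

test_result <- function(test, statistic, p_value, n, method, df = NA_real_) {
  structure(list(test = test, statistic = statistic, df = df,
                 p_value = p_value, n = n, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<%s: %s = %.4g%s, p = %.4g (%s), n = %s>\n",
              x$test, names(x$statistic)[1], x$statistic[[1]],
              if (is.finite(x$df)) sprintf(", df = %g", x$df) else "",
              x$p_value, x$method, paste(x$n, collapse = " + ")))
  invisible(x)
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Two-sided rank-sum test with midrank tie handling. The statistic W is
#' the Mann-Whitney U of the first sample (rank sum of `a` minus its
#' minimum). For combined sample sizes up to `exact_threshold` the p-value
#' is computed by full enumeration of all group assignments of the pooled
#' midranks (valid under ties); larger samples use the normal approximation
#' with tie-corrected variance and a 0.5 continuity correction.
#'
#' @param a,b Non-empty numeric samples; `a` is the focal sample.
#' @param exact_threshold Maximum combined n for exact enumeration.
#' @return A `test_result` with statistic `W`, the two-sided p-value,
#'   per-group n and the method label.
#' @export
rank_sum_test <- function(a, b, exact_threshold = 12L) {
  if (length(a) == 0L || length(b) == 0L) {
    stop_fadseed("both samples must be non-empty", "fadseed_invalid_input")
  }
  if (any(!is.finite(c(a, b)))) {
    stop_fadseed("samples must be finite numbers", "fadseed_invalid_input")
  }
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  r <- rank(c(a, b))  # midranks
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  E <- n1 * n2 / 2
  if (n <= exact_threshold) {
    picks <- combn(n, n1)
    u_perm <- colSums(matrix(r[picks], nrow = n1)) - n1 * (n1 + 1) / 2
    p <- mean(abs(u_perm - E) >= abs(U - E) - 1e-9)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    sigma2 <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (abs(U - E) - 0.5) / sqrt(sigma2)
      p <- min(1, 2 * pnorm(-max(z, 0)))
    }
    method <- "normal approximation, tie-corrected, continuity-corrected"
  }
  test_result("wilcoxon_rank_sum", c(W = U), p, c(n1 = n1, n2 = n2), method)
}

#' Two-group log-rank test
#'
#' Standard observed-minus-expected log-rank chi-square with 1 degree of
#' freedom; censoring is handled through the at-risk sets. Computed via
#' \pkg{survival}.
#'
#' @param records Tibble with columns category (two levels), day,
#'   germinated (event indicator).
#' @return A `test_result` with statistic `chisq`, df = 1 and the two-sided
#'   p-value.
#' @export
logrank_test <- function(records) {
  records <- validate_germination(records)
  if (length(unique(records$category)) != 2L) {
    stop_fadseed("log-rank test requires exactly two categories",
                 "fadseed_invalid_input")
  }
  if (sum(records$germinated) == 0L) {
    stop_fadseed("no events: log-rank test undefined", "fadseed_invalid_input")
  }
  sd_ <- survival::survdiff(
    survival::Surv(day, germinated) ~ category, data = records)
  chisq <- unname(sd_$chisq)
  test_result("logrank", c(chisq = chisq),
              pchisq(chisq, df = 1, lower.tail = FALSE),
              table(records$category), "observed minus expected", df = 1)
}

#' Per-category germination fraction
#'
#' @param records Tibble with columns category and germinated; censored
#'   (non-germinated) rows count in the denominator only.
#' @return A tibble with columns category, n, n_germinated, fraction.
#' @export
germination_summary <- function(records) {
  if (nrow(records) == 0L) {
    stop_fadseed("germination table is empty", "fadseed_invalid_input")
  }
  records |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(n = dplyr::n(),
                     n_germinated = sum(.data$germinated),
                     fraction = mean(.data$germinated),
                     .groups = "drop")
}
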