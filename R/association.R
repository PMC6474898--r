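#' Ordinary least-squares fit of y on x
#'
#' Plant-level association between mean seed spot cover (y) and the total
#' flower-count fitness proxy (x). The slope t statistic and two-sided
#' p-value use the slope standard error with n - 2 degrees of freedom. A
#' constant response yields slope 0 and R-squared 0 by convention.
#'
#' @param x,y Equal-length numeric vectors; `x` must not be constant and
#'   n >= 3.
#' @return A list of class `regression_fit`: slope, intercept, slope_se,
#'   t, p_value, r_squared, n.
#' @export
fit_linear <- function(x, y) {
  if (length(x) != length(y)) {
    stop_fadseed("x and y lengths differ", "fadseed_invalid_input")
  }
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop_fadseed("need at least 3 observations", "fadseed_invalid_input")
  if (var(x) == 0) stop_fadseed("x is constant; slope is undefined",
                                "fadseed_invalid_input")
  if (var(y) == 0) {
    return(structure(list(slope = 0, intercept = y[1], slope_se = 0,
                          t = 0, p_value = 1, r_squared = 0, n = n),
                     class = "regression_fit"))
  }
  fit <- lm(y ~ x)
  # an exactly collinear y triggers a benign "perfect fit" summary warning
  s <- suppressWarnings(summary(fit))
  co <- s$coefficients
  structure(list(
    slope = unname(co["x", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    slope_se = unname(co["x", "Std. Error"]),
    t = unname(co["x", "t value"]),
    p_value = unname(co["x", "Pr(>|t|)"]),
    r_squared = s$r.squared,
    n = n), class = "regression_fit")
}

#' @export
print.regression_fit <- function(x, ...) {
  cat(sprintf(
    "<regression_fit: slope %.4g (SE %.3g), t = %.3g, p = %.3g, R^2 = %.3g, n = %d>\n",
    x$slope, x$slope_se, x$t, x$p_value, x$r_squared, x$n))
  invisible(x)
}

#' Random-intercept linear regression
#'
#' Seed-level association (e.g. spot cover on seed area) with a per-plant
#' random intercept, fitted by restricted maximum likelihood via
#' \pkg{lme4}. When the grouping is degenerate (a single group, or the
#' random-intercept variance is estimated at 0) the fixed slope coincides
#' with the pooled OLS slope; a single group falls back to [fit_linear()]
#' with a warning.
#'
#' @param y Response vector.
#' @param x Covariate vector.
#' @param group Grouping labels (e.g. plant ids).
#' @return A list of class `mixed_fit`: slope, intercept,
#'   random_intercept_var, residual_var, t, group_name, n_obs, n_groups,
#'   method.
#' @export
fit_mixed_linear <- function(y, x, group) {
  if (length(y) != length(x) || length(y) != length(group)) {
    stop_fadseed("y, x and group lengths differ", "fadseed_invalid_input")
  }
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2L) {
    warning("single group: falling back to pooled OLS")
    f <- fit_linear(x, y)
    return(structure(list(
      slope = f$slope, intercept = f$intercept,
      random_intercept_var = NA_real_,
      residual_var = NA_real_, t = f$t, group_name = "group",
      n_obs = f$n, n_groups = 1L, method = "OLS fallback"),
      class = "mixed_fit"))
  }
  if (max(table(group)) < 2L) {
    # all groups of size 1: random intercept unidentifiable; pooled OLS
    f <- fit_linear(x, y)
    return(structure(list(
      slope = f$slope, intercept = f$intercept,
      random_intercept_var = 0, residual_var = NA_real_, t = f$t,
      group_name = "group", n_obs = f$n, n_groups = nlevels(group),
      method = "OLS (singleton groups)"), class = "mixed_fit"))
  }
  dat <- data.frame(y = y, x = x, group = group)
  fit <- suppressMessages(lme4::lmer(
    y ~ x + (1 | group), data = dat, REML = TRUE,
    control = lme4::lmerControl(check.conv.singular = "ignore")))
  vc <- as.data.frame(lme4::VarCorr(fit))
  co <- summary(fit)$coefficients
  structure(list(
    slope = unname(co["x", "Estimate"]),
    intercept = unname(co["(Intercept)", "Estimate"]),
    random_intercept_var = vc$vcov[vc$grp == "group"],
    residual_var = vc$vcov[vc$grp == "Residual"],
    t = unname(co["x", "t value"]),
    group_name = "group",
    n_obs = nrow(dat), n_groups = nlevels(group),
    method = "REML"), class = "mixed_fit")
}

#' @export
print.mixed_fit <- function(x, ...) {
  cat(sprintf(
    "<mixed_fit (%s): slope %.4g, t = %.3g, var(intercept) = %.3g, var(resid) = %.3g, %d obs / %d groups>\n",
    x$method, x$slope, x$t, x$random_intercept_var, x$residual_var,
    x$n_obs, x$n_groups))
  invisible(x)
}

#' Compare a measurement between two regimes (rank-sum)
#'
#' Nonparametric two-sample comparison of e.g. spot cover or elaiosome area
#' between light regimes; delegates to the shared [rank_sum_test()].
#'
#' @param a,b Numeric samples.
#' @param ... Passed to [rank_sum_test()].
#' @return A `test_result` (see [rank_sum_test()]).
#' @export
compare_groups <- function(a, b, ...) {
  rank_sum_test(a, b, ...)
}
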