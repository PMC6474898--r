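validate_trials <- function(trials) {
  if (!"removed_category" %in% names(trials)) {
    stop_fadseed("trials table needs a removed_category column",
                 "fadseed_invalid_input")
  }
  if (nrow(trials) == 0L) {
    stop_fadseed("no trials", "fadseed_invalid_input")
  }
  bad <- setdiff(unique(trials$removed_category), c("unspotted", "spotted"))
  if (length(bad) > 0L) {
    stop_fadseed(sprintf("unknown removed_category value(s): %s",
                         paste(bad, collapse = ", ")),
                 "fadseed_invalid_input")
  }
  trials
}

preference_result <- function(removals, focal, fraction, odds_ratio,
                              statistic, p_value, method, extra = list()) {
  structure(c(list(removals = removals, focal = focal,
                   preference_fraction = fraction, odds_ratio = odds_ratio,
                   statistic = statistic, p_value = p_value,
                   method = method), extra),
            class = "preference_result")
}

#' @export
print.preference_result <- function(x, ...) {
  cat(sprintf(
    "<preference_result (%s): %s removed in %.1f%% of %d trials, OR = %.3g, p = %.3g>\n",
    x$method, x$focal, 100 * x$preference_fraction, sum(x$removals),
    x$odds_ratio, x$p_value))
  invisible(x)
}

#' Paired-trial removal preference
#'
#' Per-category removal fraction (count / total trials), a two-sided exact
#' binomial sign test against the category-blind null of 0.5, and the raw
#' odds ratio of removal, defined as spotted removals / unspotted removals
#' (so preference for unspotted seeds gives OR < 1).
#'
#' @param trials Tibble with a removed_category column
#'   (unspotted / spotted), one row per trial.
#' @param focal Category whose removal fraction is reported (default
#'   unspotted).
#' @return A `preference_result`: removals (named counts),
#'   preference_fraction (focal), odds_ratio, statistic (focal count),
#'   p_value, method.
#' @export
trial_preference <- function(trials, focal = "unspotted") {
  trials <- validate_trials(trials)
  focal <- match.arg(focal, c("unspotted", "spotted"))
  other <- setdiff(c("unspotted", "spotted"), focal)
  n <- nrow(trials)
  k <- sum(trials$removed_category == focal)
  removals <- setNames(c(k, n - k), c(focal, other))
  bt <- binom.test(k, n, p = 0.5, alternative = "two.sided")
  or <- removals[["spotted"]] / removals[["unspotted"]]
  preference_result(removals, focal, k / n, or,
                    setNames(k, paste0("n_", focal)), bt$p.value,
                    "exact binomial sign test")
}

#' Mixed-effects logistic preference model
#'
#' Intercept-only logistic regression of the binary outcome "the spotted
#' seed was removed", with a random intercept per time point, fitted via
#' \pkg{lme4}. The reported odds ratio exp(intercept) is the conditional
#' odds of a spotted removal; with zero between-time-point variance it
#' coincides with the raw odds ratio of [trial_preference()].
#'
#' @param trials Tibble with columns removed_category and a time-point
#'   grouping column.
#' @param time_col Name of the grouping column (default "time"); the random
#'   intercept has one level per distinct value.
#' @return A `preference_result` with odds_ratio, Wald z statistic, p-value
#'   and random_intercept_sd.
#' @export
trial_mixed_logistic <- function(trials, time_col = "time") {
  trials <- validate_trials(trials)
  if (!time_col %in% names(trials)) {
    stop_fadseed(sprintf("trials table has no '%s' column", time_col),
                 "fadseed_invalid_input")
  }
  y <- as.integer(trials$removed_category == "spotted")
  if (all(y == 1L) || all(y == 0L)) {
    stop_fadseed("complete separation: every trial removed the same category",
                 "fadseed_separation")
  }
  tp <- as.factor(as.character(trials[[time_col]]))
  if (nlevels(tp) < 2L) {
    stop_fadseed("at least 2 time points are required", "fadseed_invalid_input")
  }
  dat <- data.frame(y = y, tp = tp)
  fit <- suppressMessages(lme4::glmer(
    y ~ 1 + (1 | tp), data = dat, family = stats::binomial(),
    control = lme4::glmerControl(check.conv.singular = "ignore")))
  co <- summary(fit)$coefficients
  est <- co["(Intercept)", "Estimate"]
  z <- co["(Intercept)", "z value"]
  p <- co["(Intercept)", "Pr(>|z|)"]
  vc <- as.data.frame(lme4::VarCorr(fit))
  n <- nrow(trials)
  k_sp <- sum(y)
  preference_result(
    setNames(c(n - k_sp, k_sp), c("unspotted", "spotted")),
    "spotted", k_sp / n, exp(est), c(z = z), p,
    "mixed-effects logistic regression (random intercept per time point)",
    extra = list(random_intercept_sd = sqrt(vc$vcov[1]),
                 n_time_points = nlevels(tp)))
}

#' Checkerboard grid assay
#'
#' Bundles a grid layout (cell categories in a proper checkerboard
#' 2-coloring) with an ordered removal log. Validated invariants: the
#' layout is a proper 2-coloring, every event references an occupied cell,
#' no cell is removed twice, and event indices are strictly increasing.
#'
#' @param layout Tibble with columns row, col (0-based), category.
#' @param events Tibble with columns event_index, time, row, col, ordered
#'   removals.
#' @return An object of class `grid_assay` with elements layout, events
#'   (events gain a category column joined from the layout).
#' @export
grid_assay <- function(layout, events) {
  need_l <- c("row", "col", "category")
  need_e <- c("event_index", "time", "row", "col")
  if (!all(need_l %in% names(layout)) || !all(need_e %in% names(events))) {
    stop_fadseed("layout needs row/col/category; events need event_index/time/row/col",
                 "fadseed_invalid_input")
  }
  key <- paste(layout$row, layout$col)
  if (anyDuplicated(key)) {
    stop_fadseed("duplicate cells in layout", "fadseed_invalid_input")
  }
  # proper 2-coloring: orthogonal neighbors always differ
  cat_of <- setNames(layout$category, key)
  for (d in list(c(0, 1), c(1, 0))) {
    nb <- paste(layout$row + d[1], layout$col + d[2])
    present <- nb %in% key
    if (any(layout$category[present] == cat_of[nb[present]])) {
      stop_fadseed("layout is not a proper checkerboard 2-coloring",
                   "fadseed_invalid_input")
    }
  }
  ekey <- paste(events$row, events$col)
  if (!all(ekey %in% key)) {
    stop_fadseed("removal event references a cell not in the layout",
                 "fadseed_data_integrity")
  }
  if (anyDuplicated(ekey)) {
    stop_fadseed("a cell is removed more than once", "fadseed_data_integrity")
  }
  if (nrow(events) > 1L && any(diff(events$event_index) <= 0)) {
    stop_fadseed("event indices must be strictly increasing",
                 "fadseed_data_integrity")
  }
  events$category <- unname(cat_of[ekey])
  structure(list(layout = tibble::as_tibble(layout),
                 events = tibble::as_tibble(events)),
            class = "grid_assay")
}

#' @export
print.grid_assay <- function(x, ...) {
  cat(sprintf("<grid_assay: %d cells (%s), %d removal events>\n",
              nrow(x$layout),
              paste(sprintf("%d %s", table(x$layout$category),
                            names(table(x$layout$category))), collapse = ", "),
              nrow(x$events)))
  invisible(x)
}

#' Grid composition after the first k removals
#'
#' Applies the first `k` events of the removal log to the initial layout
#' and reports removed and remaining seed counts per category. Removed plus
#' remaining always equals the initial composition.
#'
#' @param assay A [grid_assay()].
#' @param k Number of removals to apply, between 0 and the number of
#'   occupied cells.
#' @return A list with named integer vectors `removed` and `remaining`, and
#'   `k`.
#' @export
grid_state <- function(assay, k) {
  stopifnot(inherits(assay, "grid_assay"))
  assert_scalar_number(k, "k", min = 0, max = nrow(assay$layout))
  k <- as.integer(k)
  if (k > nrow(assay$events)) {
    stop_fadseed(sprintf("k = %d exceeds the %d logged removals",
                         k, nrow(assay$events)), "fadseed_invalid_input")
  }
  cats <- sort(unique(assay$layout$category))
  initial <- setNames(as.integer(table(factor(assay$layout$category, cats))),
                      cats)
  removed_cat <- factor(assay$events$category[seq_len(k)], cats)
  removed <- setNames(as.integer(table(removed_cat)), cats)
  list(removed = removed, remaining = initial - removed, k = k)
}

#' Rank-sum test on grid removal order
#'
#' Ranks removals by event order (1 = first removed), splits ranks by seed
#' category and compares them with the shared [rank_sum_test()]
#' implementation, unspotted ranks first. Seeds never removed are excluded;
#' a category with no removals is an error.
#'
#' @param assay A [grid_assay()].
#' @param ... Passed to [rank_sum_test()].
#' @return A `test_result`.
#' @export
grid_rank_test <- function(assay, ...) {
  stopifnot(inherits(assay, "grid_assay"))
  ranks <- seq_len(nrow(assay$events))
  cat_ <- assay$events$category
  if (!all(c("unspotted", "spotted") %in% cat_)) {
    stop_fadseed(paste(
      "a category was never removed; the removal-order rank test needs",
      "removals from both categories (censored-rank analysis is not supported)"),
      "fadseed_invalid_input")
  }
  rank_sum_test(ranks[cat_ == "unspotted"], ranks[cat_ == "spotted"], ...)
}

#' Category-blind removal null for the grid assay
#'
#' Upper-tail probability of removing at least `observed` seeds of the
#' focal category in `draws` category-blind draws without replacement from
#' a layout with `focal_total` focal seeds out of `grand_total`
#' (hypergeometric tail).
#'
#' @param observed Observed number of focal-category removals.
#' @param draws Total number of removals.
#' @param focal_total Focal-category seeds initially on the grid.
#' @param grand_total All seeds initially on the grid.
#' @return P(X >= observed) under the hypergeometric null.
#' @export
random_removal_null <- function(observed, draws, focal_total, grand_total) {
  for (v in c(observed, draws, focal_total, grand_total)) {
    assert_scalar_number(v, "counts", min = 0)
  }
  if (focal_total > grand_total || draws > grand_total) {
    stop_fadseed("counts inconsistent with the layout", "fadseed_invalid_input")
  }
  if (observed > draws) {
    stop_fadseed("observed removals exceed the number of draws",
                 "fadseed_invalid_input")
  }
  phyper(observed - 1, focal_total, grand_total - focal_total, draws,
         lower.tail = FALSE)
}
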