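#' Plant fitness proxy: total flowers excluding the top whorl
#'
#' The total flower count of a plant is used as its fitness proxy. The top
#' (last) whorl is omitted because its development is typically partial at
#' harvest. A single-whorl plant therefore has fitness 0 (only the omitted
#' whorl exists); this boundary case is flagged with a message rather than
#' an error.
#'
#' @param whorl_flowers Ordered (base to top) vector of non-negative integer
#'   flower counts, one per whorl.
#' @return Total flowers over all whorls except the last.
#' @export
plant_fitness <- function(whorl_flowers) {
  if (length(whorl_flowers) == 0L) {
    stop_fadseed("whorl list is empty", "fadseed_invalid_input")
  }
  if (!is.numeric(whorl_flowers) || any(!is.finite(whorl_flowers)) ||
      any(whorl_flowers < 0) || any(whorl_flowers != round(whorl_flowers))) {
    stop_fadseed("whorl flower counts must be non-negative integers",
                 "fadseed_invalid_input")
  }
  if (length(whorl_flowers) == 1L) {
    message("plant_fitness: single-whorl plant; fitness is 0 by the top-whorl omission rule")
  }
  sum(head(whorl_flowers, -1L))
}

#' Classify seeds into spot-cover extremes by rank
#'
#' Labels the lowest-ranked `floor(low_quantile * n)` covers "unspotted" and
#' the highest-ranked `floor((1 - high_quantile) * n)` covers "spotted"; the
#' remainder is "mid". Classification is rank-based (not value-threshold
#' based), so it is permutation-invariant for distinct values; ties spanning
#' a cut are broken by stable input order and logged with a message.
#'
#' @param covers Numeric vector of percent spot covers.
#' @param low_quantile Lower tail mass defining "unspotted" (default 0.15).
#' @param high_quantile Upper cut defining "spotted" (default 0.85; the tail
#'   mass is `1 - high_quantile`).
#' @return A character vector with levels unspotted / mid / spotted, in
#'   input order.
#' @export
categorize_seeds <- function(covers, low_quantile = 0.15,
                             high_quantile = 0.85) {
  assert_scalar_number(low_quantile, "low_quantile", min = 0, max = 0.5)
  assert_scalar_number(high_quantile, "high_quantile", min = 0.5, max = 1)
  n <- length(covers)
  if (n < 7L) {
    stop_fadseed("at least 7 values are required so both tails are non-empty",
                 "fadseed_invalid_input")
  }
  if (!is.numeric(covers) || any(!is.finite(covers))) {
    stop_fadseed("covers must be finite numbers", "fadseed_invalid_input")
  }
  if (length(unique(covers)) == 1L) {
    stop_fadseed("degenerate distribution: all cover values identical",
                 "fadseed_degenerate")
  }
  k_low <- floor(low_quantile * n)
  k_high <- floor((1 - high_quantile) * n)
  ord <- order(covers)  # stable: ties keep input order
  labels <- rep("mid", n)
  if (k_low > 0L) {
    labels[ord[seq_len(k_low)]] <- "unspotted"
    if (covers[ord[k_low]] == covers[ord[k_low + 1L]]) {
      message("categorize_seeds: ties span the lower cut; broken by input order")
    }
  }
  if (k_high > 0L) {
    labels[ord[seq(n - k_high + 1L, n)]] <- "spotted"
    if (covers[ord[n - k_high + 1L]] == covers[ord[n - k_high]]) {
      message("categorize_seeds: ties span the upper cut; broken by input order")
    }
  }
  labels
}

#' Aggregate seed records to plant level
#'
#' Per plant: mean and unbiased (n-1) variance of spot cover, mean elaiosome
#' area and seed count. A plant with a single seed gets a missing variance
#' (NA), never 0.
#'
#' @param seeds A tibble with columns plant_id, spot_cover_pct, and
#'   optionally elaiosome_area_px.
#' @return A tibble with one row per plant: plant_id, n_seeds, mean_cover,
#'   var_cover, mean_elaiosome.
#' @export
aggregate_plants <- function(seeds) {
  if (!all(c("plant_id", "spot_cover_pct") %in% names(seeds))) {
    stop_fadseed("seeds table needs columns plant_id and spot_cover_pct",
                 "fadseed_invalid_input")
  }
  if (anyNA(seeds$plant_id)) {
    stop_fadseed("every seed row must carry a plant identifier",
                 "fadseed_invalid_input")
  }
  el <- if ("elaiosome_area_px" %in% names(seeds)) {
    seeds$elaiosome_area_px
  } else {
    rep(NA_real_, nrow(seeds))
  }
  seeds |>
    dplyr::mutate(.elaiosome = el) |>
    dplyr::group_by(.data$plant_id) |>
    dplyr::summarise(
      n_seeds = dplyr::n(),
      mean_cover = mean(.data$spot_cover_pct),
      var_cover = if (dplyr::n() > 1L) var(.data$spot_cover_pct) else NA_real_,
      mean_elaiosome = mean(.elaiosome),
      .groups = "drop")
}
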