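#' Parameters for the synthetic plant-population generator
#'
#' Defines a population in which a plant's expected mean seed spot cover
#' increases linearly with its total flower count (the fitness proxy).
#' Defaults emulate the study scale: 30 plants, 12-20 whorls each (one seed
#' per whorl, so about 480 seeds), Poisson(6) flowers per whorl, slope
#' 0.078 percent cover per flower and plant-level noise calibrated to give
#' a plant-level regression R-squared near 0.24.
#'
#' @param n_plants Number of plants (>= 2).
#' @param whorl_range Integer range (min, max) of whorls per plant; one seed
#'   row is produced per whorl.
#' @param flowers_lambda Poisson mean of the per-whorl flower count.
#' @param slope Regression slope of plant mean spot cover on total flowers,
#'   in percent cover per flower.
#' @param intercept Intercept of that line, in percent cover.
#' @param plant_noise_sd Plant-level s.d. of mean cover about the line.
#' @param seed_noise_sd Within-plant s.d. of individual seed covers about
#'   the plant mean.
#' @param regime Light-regime label attached to every record.
#' @param seed Integer RNG seed.
#' @return An object of class `population_gen_params`.
#' @export
population_gen_params <- function(n_plants = 30L,
                                  whorl_range = c(12L, 20L),
                                  flowers_lambda = 6,
                                  slope = 0.078, intercept = 23,
                                  plant_noise_sd = 2.5,
                                  seed_noise_sd = 5,
                                  regime = "low",
                                  seed = 1L) {
  assert_scalar_number(n_plants, "n_plants", min = 2)
  assert_scalar_number(slope, "slope")
  assert_scalar_number(plant_noise_sd, "plant_noise_sd", min = 0)
  assert_scalar_number(seed_noise_sd, "seed_noise_sd", min = 0)
  assert_scalar_number(seed, "seed")
  whorl_range <- as.integer(whorl_range)
  if (length(whorl_range) != 2L || any(whorl_range < 1L) ||
      whorl_range[1] > whorl_range[2]) {
    stop_fadseed("`whorl_range` must be an increasing pair of positive integers",
                 "fadseed_invalid_params")
  }
  structure(list(
    n_plants = as.integer(n_plants), whorl_range = whorl_range,
    flowers_lambda = flowers_lambda, slope = slope, intercept = intercept,
    plant_noise_sd = plant_noise_sd, seed_noise_sd = seed_noise_sd,
    regime = regime, seed = as.integer(seed)
  ), class = "population_gen_params")
}

#' Generate a fitness-correlated synthetic plant population
#'
#' Draws whorl structures and per-whorl flower counts per plant, computes
#' the fitness proxy (total flowers excluding the top whorl, see
#' [plant_fitness()]), sets each plant's expected mean seed spot cover to
#' `intercept + slope * total_flowers` plus plant-level noise, and draws one
#' seed per whorl around that mean. Covers are clipped to \[0, 100\].
#' Seed area and elaiosome area are drawn as independent Gaussian
#' morphometric noise so downstream schemas are complete.
#'
#' @param params A [population_gen_params()] object.
#' @return A list with tibbles `plants` (plant_id, regime, n_whorls,
#'   total_flowers, true_mean_cover) and `seeds` (seed_id, plant_id,
#'   whorl_index, seed_area_px, spot_area_px, spot_cover_pct,
#'   elaiosome_area_px).
#' @export
generate_population <- function(params) {
  stopifnot(inherits(params, "population_gen_params"))
  p <- params
  withr::with_seed(p$seed, {
    whorl_choices <- seq(p$whorl_range[1], p$whorl_range[2])
    n_whorls <- whorl_choices[sample.int(length(whorl_choices),
                                         p$n_plants, replace = TRUE)]
    plant_id <- sprintf("%s_plant_%02d", p$regime, seq_len(p$n_plants))
    total_flowers <- integer(p$n_plants)
    seed_rows <- vector("list", p$n_plants)
    plant_mean <- numeric(p$n_plants)
    for (i in seq_len(p$n_plants)) {
      flowers <- rpois(n_whorls[i], p$flowers_lambda)
      total_flowers[i] <- plant_fitness(flowers)
      mu <- p$intercept + p$slope * total_flowers[i] +
        rnorm(1, sd = p$plant_noise_sd)
      plant_mean[i] <- mu
      covers <- pmin(pmax(mu + rnorm(n_whorls[i], sd = p$seed_noise_sd), 0), 100)
      seed_area <- pmax(round(rnorm(n_whorls[i], 10000, 800)), 1000)
      elaiosome <- pmax(round(rnorm(n_whorls[i], 900, 100)), 100)
      seed_rows[[i]] <- tibble::tibble(
        seed_id = sprintf("%s_w%02d", plant_id[i], seq_len(n_whorls[i])),
        plant_id = plant_id[i],
        whorl_index = seq_len(n_whorls[i]),
        flowers_in_whorl = flowers,
        seed_area_px = seed_area,
        spot_area_px = round(seed_area * covers / 100),
        spot_cover_pct = covers,
        elaiosome_area_px = elaiosome
      )
    }
    list(
      plants = tibble::tibble(
        plant_id = plant_id, regime = p$regime, n_whorls = n_whorls,
        total_flowers = total_flowers, true_mean_cover = plant_mean),
      seeds = dplyr::bind_rows(seed_rows)
    )
  })
}

#' Parameters for the synthetic germination generator
#'
#' Each category germinates with its own probability; germination day is
#' lognormal (truncated at the study horizon by inverse-CDF sampling so the
#' germinated fraction is exactly Bernoulli-driven). Non-germinating seeds
#' are right-censored at the horizon. Defaults emulate the study scale:
#' 108 seeds per category, germination probabilities 0.74 (unspotted) and
#' 0.898 (spotted), with the unspotted category more variable in time.
#'
#' @param n_per_category Seeds per category.
#' @param p_germ Named vector of germination probabilities per category.
#' @param meanlog,sdlog Named vectors of lognormal location/spread of
#'   germination day per category.
#' @param horizon Study end (days); censoring time for non-germinators.
#' @param seed Integer RNG seed.
#' @return An object of class `germination_gen_params`.
#' @export
germination_gen_params <- function(n_per_category = 108L,
                                   p_germ = c(unspotted = 0.74, spotted = 0.898),
                                   meanlog = c(unspotted = log(7), spotted = log(6)),
                                   sdlog = c(unspotted = 0.6, spotted = 0.3),
                                   horizon = 30,
                                   seed = 1L) {
  assert_scalar_number(n_per_category, "n_per_category", min = 1)
  assert_scalar_number(horizon, "horizon", min = 0)
  assert_scalar_number(seed, "seed")
  if (any(p_germ < 0 | p_germ > 1)) {
    stop_fadseed("germination probabilities must be in [0, 1]",
                 "fadseed_invalid_params")
  }
  cats <- names(p_germ)
  if (is.null(cats) || !setequal(cats, names(meanlog)) ||
      !setequal(cats, names(sdlog))) {
    stop_fadseed("p_germ, meanlog and sdlog must share category names",
                 "fadseed_invalid_params")
  }
  if (any(sdlog < 0)) {
    stop_fadseed("sdlog must be non-negative", "fadseed_invalid_params")
  }
  structure(list(n_per_category = as.integer(n_per_category), p_germ = p_germ,
                 meanlog = meanlog, sdlog = sdlog, horizon = horizon,
                 seed = as.integer(seed)),
            class = "germination_gen_params")
}

#' Generate a synthetic germination table
#'
#' @param params A [germination_gen_params()] object.
#' @return A tibble with columns seed_id, category, day, germinated
#'   (logical; `FALSE` rows are right-censored at the horizon).
#' @export
generate_germination <- function(params) {
  stopifnot(inherits(params, "germination_gen_params"))
  p <- params
  withr::with_seed(p$seed, {
    rows <- lapply(names(p$p_germ), function(cat) {
      n <- p$n_per_category
      germ <- runif(n) < p$p_germ[[cat]]
      # truncated-lognormal day for germinators (inverse CDF)
      u <- runif(n)
      if (p$sdlog[[cat]] == 0) {
        day <- rep(exp(p$meanlog[[cat]]), n)
      } else {
        fmax <- stats::plnorm(p$horizon, p$meanlog[[cat]], p$sdlog[[cat]])
        day <- qlnorm(u * fmax, p$meanlog[[cat]], p$sdlog[[cat]])
      }
      day <- pmin(day, p$horizon)
      day[!germ] <- p$horizon
      tibble::tibble(
        seed_id = sprintf("%s_%04d", cat, seq_len(n)),
        category = cat, day = day, germinated = germ)
    })
    dplyr::bind_rows(rows)
  })
}

#' Parameters for the synthetic paired-trial generator
#'
#' Each trial presents one unspotted and one spotted seed; one is removed.
#' The removal is Bernoulli with session-level heterogeneity on the logit
#' scale. Defaults emulate the study scale: 212 trials over 3 sessions.
#'
#' @param n_trials Total number of trials.
#' @param p_unspotted Baseline probability that the unspotted seed is the one
#'   removed.
#' @param n_sessions Number of sessions (days); trials are spread evenly.
#' @param session_sd S.d. of the session random effect on the logit scale.
#' @param seed Integer RNG seed.
#' @return An object of class `trial_gen_params`.
#' @export
trial_gen_params <- function(n_trials = 212L, p_unspotted = 0.608,
                             n_sessions = 3L, session_sd = 0,
                             seed = 1L) {
  assert_scalar_number(n_trials, "n_trials", min = 1)
  assert_scalar_number(p_unspotted, "p_unspotted", min = 0, max = 1)
  assert_scalar_number(n_sessions, "n_sessions", min = 1)
  assert_scalar_number(session_sd, "session_sd", min = 0)
  assert_scalar_number(seed, "seed")
  structure(list(n_trials = as.integer(n_trials), p_unspotted = p_unspotted,
                 n_sessions = as.integer(n_sessions), session_sd = session_sd,
                 seed = as.integer(seed)),
            class = "trial_gen_params")
}

#' Generate a synthetic paired-trial removal log
#'
#' @param params A [trial_gen_params()] object.
#' @return A tibble with columns trial_id, session, time, removed_category;
#'   exactly one removed category per trial.
#' @export
generate_trials <- function(params) {
  stopifnot(inherits(params, "trial_gen_params"))
  p <- params
  withr::with_seed(p$seed, {
    session <- rep(seq_len(p$n_sessions), length.out = p$n_trials)
    session <- sort(session)
    eff <- rnorm(p$n_sessions, sd = p$session_sd)
    eta <- stats::qlogis(min(max(p$p_unspotted, 1e-12), 1 - 1e-12)) +
      eff[session]
    take_unspotted <- runif(p$n_trials) < stats::plogis(eta)
    tibble::tibble(
      trial_id = seq_len(p$n_trials),
      session = sprintf("session_%d", session),
      time = stats::ave(seq_len(p$n_trials), session, FUN = seq_along),
      removed_category = ifelse(take_unspotted, "unspotted", "spotted"))
  })
}

#' Parameters for the synthetic checkerboard-grid generator
#'
#' Seeds of the two categories alternate on an even-sided square grid.
#' Removals are sequential: while both categories remain, the next removal
#' is unspotted with probability `preference`, and the removed cell is drawn
#' uniformly within the chosen category.
#'
#' @param side Grid side; must be even so the checkerboard is balanced.
#' @param preference Probability that the next removal is unspotted when
#'   both categories remain (0.5 = category-blind).
#' @param n_removals Number of removal events to log; defaults to all cells.
#' @param seed Integer RNG seed.
#' @return An object of class `grid_gen_params`.
#' @export
grid_gen_params <- function(side = 8L, preference = 0.5,
                            n_removals = NULL, seed = 1L) {
  assert_scalar_number(side, "side", min = 2)
  assert_scalar_number(preference, "preference", min = 0, max = 1)
  assert_scalar_number(seed, "seed")
  side <- as.integer(side)
  if (side %% 2L != 0L) {
    stop_fadseed("grid side must be even for a balanced checkerboard",
                 "fadseed_invalid_params")
  }
  n_removals <- as.integer(n_removals %||% (side * side))
  assert_scalar_number(n_removals, "n_removals", min = 0, max = side * side)
  structure(list(side = side, preference = preference,
                 n_removals = n_removals, seed = as.integer(seed)),
            class = "grid_gen_params")
}

#' Generate a synthetic checkerboard-grid removal assay
#'
#' @param params A [grid_gen_params()] object.
#' @return A [grid_assay()] whose layout is a proper checkerboard 2-coloring
#'   and whose event log is a permutation of the removed cells.
#' @export
generate_grid <- function(params) {
  stopifnot(inherits(params, "grid_gen_params"))
  p <- params
  layout <- expand.grid(row = seq_len(p$side) - 1L, col = seq_len(p$side) - 1L)
  layout$category <- ifelse((layout$row + layout$col) %% 2L == 0L,
                            "unspotted", "spotted")
  layout <- tibble::as_tibble(layout)
  withr::with_seed(p$seed, {
    remaining <- split(seq_len(nrow(layout)), layout$category)
    events <- vector("list", p$n_removals)
    for (k in seq_len(p$n_removals)) {
      have_u <- length(remaining$unspotted) > 0L
      have_s <- length(remaining$spotted) > 0L
      cat_k <- if (have_u && have_s) {
        if (runif(1) < p$preference) "unspotted" else "spotted"
      } else if (have_u) "unspotted" else "spotted"
      pool <- remaining[[cat_k]]
      idx <- pool[sample.int(length(pool), 1L)]
      remaining[[cat_k]] <- setdiff(pool, idx)
      events[[k]] <- tibble::tibble(
        event_index = k, time = k,
        row = layout$row[idx], col = layout$col[idx])
    }
    grid_assay(layout, dplyr::bind_rows(events))
  })
}
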