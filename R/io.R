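#' Versioned CSV writers and readers
#'
#' All pipeline tables are written as UTF-8 CSV with a header row, "."
#' decimal separator, empty fields for missing values, and a leading
#' comment line `# fadseed schema <name> v1` that versions the schema.
#' Readers skip comment lines and preserve unknown columns.
#'
#' @param x A data frame.
#' @param path File path.
#' @param schema Short schema name recorded in the header comment.
#' @return `path` (writer) or a tibble (reader).
#' @export
write_fadseed_csv <- function(x, path, schema = "table") {
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(sprintf("# fadseed schema %s v1", schema), con)
  utils::write.table(x, con, sep = ",", row.names = FALSE, qmethod = "double",
                     na = "")
  invisible(path)
}

#' @rdname write_fadseed_csv
#' @export
read_fadseed_csv <- function(path) {
  if (!file.exists(path)) {
    stop_fadseed(sprintf("file not found: %s", path), "fadseed_io_error")
  }
  readr::read_csv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Path to a packaged example data file
#'
#' The package ships small synthetic fixture logs under `extdata/`:
#' `paired_trials_synthetic.csv` (a 212-trial paired-choice log whose
#' per-category removal totals are 129 unspotted and 83 spotted),
#' `grid_layout_synthetic.csv` and `grid_events_synthetic.csv` (an 8 x 8
#' checkerboard assay whose first 32 removals take 24 unspotted and 8
#' spotted seeds). All are synthetic reconstructions constrained to those
#' totals; the underlying raw assay logs are not public.
#'
#' @param file File name within `extdata/`; with no argument, lists the
#'   available files.
#' @return A file path, or a character vector of file names.
#' @export
fadseed_example <- function(file = NULL) {
  if (is.null(file)) {
    return(list.files(system.file("extdata", package = "fadseed")))
  }
  path <- system.file("extdata", file, package = "fadseed")
  if (path == "") {
    stop_fadseed(sprintf("no packaged example file '%s'", file),
                 "fadseed_io_error")
  }
  path
}

#' Pipeline configuration
#'
#' Validated bag of settings for [run_pipeline()]. When `simulate` is TRUE
#' every input is generated by the synthetic-data module from `seed`;
#' otherwise `paths` must name existing CSV inputs per stage.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer RNG seed used by every stochastic stage.
#' @param simulate Generate inputs synthetically (default) or read them
#'   from `paths`.
#' @param paths Named list of input CSVs (`seeds`, `germination`, `trials`,
#'   `grid_layout`, `grid_events`) when `simulate = FALSE`.
#' @param population Params for [generate_population()].
#' @param germination Params for [generate_germination()].
#' @param trials Params for [generate_trials()].
#' @param grid Params for [generate_grid()].
#' @param n_images Number of synthetic seed images rendered and segmented
#'   in the imaging-validation stage (0 disables the stage).
#' @param quantile_cut Lower-tail mass of the seed categorization, in
#'   (0, 0.5); the upper cut is symmetric.
#' @param alpha Significance level recorded with test results, in (0, 1).
#' @param exact_threshold Combined-n threshold for exact rank-sum p-values.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L, simulate = TRUE,
                            paths = list(),
                            population = NULL, germination = NULL,
                            trials = NULL, grid = NULL,
                            n_images = 6L,
                            quantile_cut = 0.15, alpha = 0.05,
                            exact_threshold = 12L) {
  assert_scalar_number(seed, "seed")
  assert_scalar_number(n_images, "n_images", min = 0)
  if (quantile_cut <= 0 || quantile_cut >= 0.5) {
    stop_fadseed("`quantile_cut` must be in (0, 0.5)", "fadseed_invalid_params")
  }
  if (alpha <= 0 || alpha >= 1) {
    stop_fadseed("`alpha` must be in (0, 1)", "fadseed_invalid_params")
  }
  seed <- as.integer(seed)
  structure(list(
    out_dir = out_dir, seed = seed, simulate = isTRUE(simulate),
    paths = paths,
    population = population %||% population_gen_params(seed = seed),
    germination = germination %||% germination_gen_params(seed = seed + 1L),
    trials = trials %||% trial_gen_params(seed = seed + 2L),
    grid = grid %||% grid_gen_params(seed = seed + 3L),
    n_images = as.integer(n_images),
    quantile_cut = quantile_cut, alpha = alpha,
    exact_threshold = as.integer(exact_threshold)
  ), class = "pipeline_config")
}

pipeline_input <- function(config, stage, reader) {
  path <- config$paths[[stage]]
  if (is.null(path) || !file.exists(path %||% "")) {
    stop_fadseed(sprintf(
      "stage '%s': input missing (no simulated data requested and no readable path given)",
      stage), "fadseed_missing_input")
  }
  reader(path)
}

#' Run the full simulate - segment - phenotype - analyze pipeline
#'
#' Executes every stage of the analysis on synthetic (or supplied) inputs
#' and writes its tables (CSV), model results (JSON) and a run log under
#' `config$out_dir`. Deterministic stages are bit-identical across reruns
#' with the same configuration.
#'
#' Outputs: `seeds.csv`, `plants.csv`, `germination.csv`, `trials.csv`,
#' `grid_layout.csv`, `grid_events.csv`, `imaging_validation.csv` (when
#' imaging is enabled), `results.json`, `run_log.txt`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a report bundle: list with elements `seeds`, `plants`,
#'   `fitness`, `germination`, `preference`, `imaging`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- c(
    sprintf("fadseed %s", as.character(utils::packageVersion("fadseed"))),
    sprintf("RNG seed: %d", config$seed),
    sprintf("simulate: %s", config$simulate))

  # --- inputs -------------------------------------------------------------
  if (config$simulate) {
    pop <- generate_population(config$population)
    seeds <- pop$seeds
    plants_gen <- pop$plants
    germ <- generate_germination(config$germination)
    trials <- generate_trials(config$trials)
    grid <- generate_grid(config$grid)
  } else {
    seeds <- pipeline_input(config, "seeds", read_fadseed_csv)
    plants_gen <- NULL
    germ <- pipeline_input(config, "germination", read_fadseed_csv)
    trials <- pipeline_input(config, "trials", read_fadseed_csv)
    grid <- grid_assay(pipeline_input(config, "grid_layout", read_fadseed_csv),
                       pipeline_input(config, "grid_events", read_fadseed_csv))
  }

  # --- imaging validation -------------------------------------------------
  imaging <- NULL
  if (config$simulate && config$n_images > 0L) {
    covers <- seq(0.05, 0.45, length.out = config$n_images)
    imaging <- dplyr::bind_rows(lapply(seq_len(config$n_images), function(i) {
      sim <- generate_seed_image(image_gen_params(
        spot_cover = covers[i], seed = config$seed + 100L + i))
      m <- measure_seed(segment_seed(sim$image))
      truth <- measure_seed(sim$masks)
      tibble::tibble(image = i, target_cover_pct = 100 * covers[i],
                     true_cover_pct = truth$spot_cover_pct,
                     recovered_cover_pct = m$spot_cover_pct)
    }))
    write_fadseed_csv(imaging, file.path(config$out_dir, "imaging_validation.csv"),
                      "imaging_validation")
    log_lines <- c(log_lines, sprintf(
      "imaging: %d synthetic seeds, mean |recovered - true| = %.3f points",
      config$n_images,
      mean(abs(imaging$recovered_cover_pct - imaging$true_cover_pct))))
  }

  # --- phenotype ----------------------------------------------------------
  seeds$category <- categorize_seeds(seeds$spot_cover_pct,
                                     low_quantile = config$quantile_cut,
                                     high_quantile = 1 - config$quantile_cut)
  plants <- aggregate_plants(seeds)
  if (!is.null(plants_gen)) {
    plants <- dplyr::left_join(
      plants, plants_gen[, c("plant_id", "regime", "n_whorls", "total_flowers")],
      by = "plant_id")
  } else if (!"total_flowers" %in% names(plants)) {
    stop_fadseed("stage 'phenotype': plant fitness requires total_flowers",
                 "fadseed_missing_input")
  }
  write_fadseed_csv(seeds, file.path(config$out_dir, "seeds.csv"), "seeds")
  write_fadseed_csv(plants, file.path(config$out_dir, "plants.csv"), "plants")

  # --- fitness association ------------------------------------------------
  fit_plant <- fit_linear(plants$total_flowers, plants$mean_cover)
  fit_seed <- fit_mixed_linear(seeds$spot_cover_pct, seeds$seed_area_px,
                               seeds$plant_id)
  seed_fitness <- dplyr::left_join(
    seeds, plants[, c("plant_id", "total_flowers")], by = "plant_id")
  cat_fitness <- seed_fitness |>
    dplyr::filter(.data$category %in% c("unspotted", "spotted")) |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(mean_fitness = mean(.data$total_flowers),
                     .groups = "drop")

  # --- germination --------------------------------------------------------
  km <- inverse_km(germ)
  gsum <- germination_summary(germ)
  lr <- logrank_test(germ)
  rs <- rank_sum_test(germ$day[germ$category == "unspotted"],
                      germ$day[germ$category == "spotted"],
                      exact_threshold = config$exact_threshold)
  write_fadseed_csv(germ, file.path(config$out_dir, "germination.csv"),
                    "germination")

  # --- preference ---------------------------------------------------------
  pref <- trial_preference(trials)
  pref_mixed <- tryCatch(trial_mixed_logistic(trials, time_col = "session"),
                         error = function(e) NULL)
  half <- floor(nrow(grid$layout) / 2)
  gstate <- grid_state(grid, min(half, nrow(grid$events)))
  grank <- grid_rank_test(grid)
  gnull <- random_removal_null(
    gstate$removed[["unspotted"]], gstate$k,
    sum(grid$layout$category == "unspotted"), nrow(grid$layout))
  write_fadseed_csv(trials, file.path(config$out_dir, "trials.csv"), "trials")
  write_fadseed_csv(grid$layout, file.path(config$out_dir, "grid_layout.csv"),
                    "grid_layout")
  write_fadseed_csv(grid$events[, c("event_index", "time", "row", "col")],
                    file.path(config$out_dir, "grid_events.csv"), "grid_events")

  results <- list(
    fitness = list(
      plant_level = unclass(fit_plant),
      seed_level_mixed = unclass(fit_seed),
      category_mean_fitness = as.list(setNames(cat_fitness$mean_fitness,
                                               cat_fitness$category))),
    germination = list(
      summary = as.list(setNames(gsum$fraction, gsum$category)),
      logrank = list(chisq = unname(lr$statistic), df = 1, p = lr$p_value),
      rank_sum = list(W = unname(rs$statistic), p = rs$p_value)),
    preference = list(
      trial = list(fraction_unspotted = pref$preference_fraction,
                   odds_ratio = pref$odds_ratio, p = pref$p_value),
      trial_mixed = if (!is.null(pref_mixed)) {
        list(odds_ratio = pref_mixed$odds_ratio, p = pref_mixed$p_value)
      },
      grid_half_state = list(removed = as.list(gstate$removed),
                             remaining = as.list(gstate$remaining)),
      grid_rank = list(W = unname(grank$statistic), p = grank$p_value),
      grid_hypergeometric_tail = gnull),
    settings = list(seed = config$seed, quantile_cut = config$quantile_cut,
                    alpha = config$alpha))
  jsonlite::write_json(results, file.path(config$out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")

  log_lines <- c(log_lines,
    sprintf("plant-level slope: %.4f (t = %.2f, p = %.3g)",
            fit_plant$slope, fit_plant$t, fit_plant$p_value),
    sprintf("germination fractions: %s",
            paste(sprintf("%s %.1f%%", gsum$category, 100 * gsum$fraction),
                  collapse = ", ")),
    sprintf("trial preference (unspotted): %.1f%%",
            100 * pref$preference_fraction))
  writeLines(log_lines, file.path(config$out_dir, "run_log.txt"))
  message(paste(log_lines, collapse = "\n"))

  invisible(list(seeds = seeds, plants = plants,
                 fitness = list(plant = fit_plant, seed_mixed = fit_seed,
                                category_fitness = cat_fitness),
                 germination = list(curves = km, summary = gsum,
                                    logrank = lr, rank_sum = rs),
                 preference = list(trial = pref, trial_mixed = pref_mixed,
                                   grid_state = gstate, grid_rank = grank,
                                   grid_null = gnull),
                 imaging = imaging))
}
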