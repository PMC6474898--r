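#' Segmentation settings
#'
#' Tunable knobs of [segment_seed()]. The pipeline is: grayscale Otsu
#' foreground/background split (seed darker than background), morphological
#' opening and closing, hole filling, largest-component selection for the
#' seed body, a second Otsu restricted to body pixels for the spots, and a
#' yellowness gate for the elaiosome. Contrast gates guard both Otsu steps:
#' Otsu always splits a histogram, so without a minimum class-separation a
#' blank image would yield a spurious seed and a spotless seed ~50% spurious
#' cover.
#'
#' @param open_radius,close_radius Disc radii (pixels) of the morphological
#'   opening/closing applied to the foreground mask.
#' @param min_seed_frac Minimum seed-candidate size as a fraction of image
#'   area; smaller components are treated as dust.
#' @param min_body_contrast Minimum background-minus-foreground grayscale
#'   separation for a foreground split to count as a seed.
#' @param min_spot_contrast Minimum within-body class separation for the
#'   spot threshold; below it the spot mask is empty.
#' @param elaiosome_yellowness Threshold on (R+G)/2 - B above which a pixel
#'   is elaiosome-candidate.
#' @param min_elaiosome_px Minimum elaiosome component size in pixels.
#' @return An object of class `seg_config`.
#' @export
seg_config <- function(open_radius = 2L, close_radius = 2L,
                       min_seed_frac = 0.005,
                       min_body_contrast = 0.10,
                       min_spot_contrast = 0.08,
                       elaiosome_yellowness = 0.15,
                       min_elaiosome_px = 40L) {
  assert_scalar_number(open_radius, "open_radius", min = 0)
  assert_scalar_number(close_radius, "close_radius", min = 0)
  assert_scalar_number(min_seed_frac, "min_seed_frac", min = 0, max = 1)
  assert_scalar_number(min_body_contrast, "min_body_contrast", min = 0, max = 1)
  assert_scalar_number(min_spot_contrast, "min_spot_contrast", min = 0, max = 1)
  assert_scalar_number(elaiosome_yellowness, "elaiosome_yellowness",
                       min = 0, max = 1)
  assert_scalar_number(min_elaiosome_px, "min_elaiosome_px", min = 0)
  structure(list(open_radius = as.integer(open_radius),
                 close_radius = as.integer(close_radius),
                 min_seed_frac = min_seed_frac,
                 min_body_contrast = min_body_contrast,
                 min_spot_contrast = min_spot_contrast,
                 elaiosome_yellowness = elaiosome_yellowness,
                 min_elaiosome_px = as.integer(min_elaiosome_px)),
            class = "seg_config")
}

image_pixels <- function(image) {
  if (inherits(image, "synthetic_seed_image")) image <- image$image
  if (is.matrix(image)) image <- array(rep(image, 3L), dim = c(dim(image), 3L))
  if (!is.array(image) || length(dim(image)) != 3L || dim(image)[3] < 3L) {
    stop_fadseed("expected an RGB image array", "fadseed_invalid_input")
  }
  unclass(image)[, , 1:3, drop = FALSE]
}

#' Segment a seed photograph into seed-body, spot and elaiosome layers
#'
#' Implements the single-seed layer decomposition: the seed body is the
#' largest dark connected component after morphological cleanup; spots are
#' the body pixels below an Otsu threshold computed over body pixels only;
#' the elaiosome is the pale, yellow-shifted component adjacent to the body
#' boundary. Expects at most one seed against a contrasting background.
#'
#' @param image A `seed_image`, `synthetic_seed_image`, or height x width x 3
#'   array in \[0, 1\].
#' @param config A [seg_config()].
#' @return A [mask_set()].
#' @export
segment_seed <- function(image, config = seg_config()) {
  stopifnot(inherits(config, "seg_config"))
  px <- image_pixels(image)
  gray <- (px[, , 1] + px[, , 2] + px[, , 3]) / 3

  thr <- otsu_threshold(as.numeric(gray))
  fg <- gray < thr
  if (!any(fg) || all(fg) ||
      mean(gray[!fg]) - mean(gray[fg]) < config$min_body_contrast) {
    stop_fadseed("no seed detected: foreground/background contrast too low",
                 "fadseed_no_seed")
  }

  m <- EBImage::Image(fg * 1)
  if (config$open_radius > 0) {
    m <- EBImage::opening(m, disc_brush(config$open_radius))
  }
  if (config$close_radius > 0) {
    m <- EBImage::closing(m, disc_brush(config$close_radius))
  }
  m <- EBImage::fillHull(m)
  fg <- matrix(as.numeric(m) > 0.5, nrow = nrow(gray))

  lab <- label_components(fg)
  sizes <- tabulate(lab[lab > 0L])
  min_px <- config$min_seed_frac * length(gray)
  cand <- which(sizes >= min_px)
  if (length(cand) == 0L) {
    stop_fadseed("no seed detected: no component above the minimum size",
                 "fadseed_no_seed")
  }
  if (length(cand) > 1L) {
    stop_fadseed(sprintf(
      "multiple candidate seeds detected (component sizes: %s px)",
      paste(sizes[cand], collapse = ", ")), "fadseed_multiple_seeds")
  }
  body <- lab == cand

  # spots: per-seed Otsu over body pixels, gated on class separation
  v <- gray[body]
  sthr <- otsu_threshold(v)
  dark <- v <= sthr
  spot <- matrix(FALSE, nrow(gray), ncol(gray))
  if (any(dark) && !all(dark) &&
      mean(v[!dark]) - mean(v[dark]) >= config$min_spot_contrast) {
    spot <- body & (gray <= sthr)
  }

  # elaiosome: yellow-shifted pale component adjacent to the body
  yellowness <- (px[, , 1] + px[, , 2]) / 2 - px[, , 3]
  em <- yellowness > config$elaiosome_yellowness & !body
  elaiosome <- matrix(FALSE, nrow(gray), ncol(gray))
  if (any(em)) {
    elab <- label_components(em)
    esz <- tabulate(elab[elab > 0L])
    keep <- which(esz >= config$min_elaiosome_px)
    if (length(keep) > 0L) {
      near <- matrix(as.numeric(EBImage::dilate(
        EBImage::Image(body * 1), disc_brush(3L))) > 0.5, nrow = nrow(gray))
      adjacent <- keep[vapply(keep, function(k) any(elab == k & near),
                              logical(1))]
      if (length(adjacent) > 0L) {
        best <- adjacent[which.max(esz[adjacent])]
        elaiosome <- elab == best
      }
    }
  }

  mask_set(body, spot, elaiosome & !body)
}

#' Morphometrics of a segmented seed
#'
#' Computes areas, the percent spot-cover statistic, centroid and bounding
#' box from a [mask_set()]. Spot cover is 100 x spot pixels / seed-body
#' pixels; the seed "total area" deliberately excludes the elaiosome (spot
#' cover is a property of the seed coat). If a physical scale (length per
#' pixel) is given, areas are also reported in physical units (scale^2 per
#' pixel). Coordinates are row-major, origin top-left, 0-based; the bounding
#' box is half-open.
#'
#' @param masks A [mask_set()].
#' @param scale Optional physical scale, length per pixel.
#' @return A list of class `seed_morphometrics` with fields `seed_area_px`,
#'   `spot_area_px`, `spot_cover_pct`, `elaiosome_area_px`, `centroid`
#'   (row, col), `bbox` (row0, row1, col0, col1, half-open) and, when
#'   `scale` is given, `seed_area`, `spot_area`, `elaiosome_area`.
#' @export
measure_seed <- function(masks, scale = NULL) {
  stopifnot(inherits(masks, "mask_set"))
  n_seed <- sum(masks$seed_body)
  if (n_seed == 0L) {
    stop_fadseed("empty seed-body mask", "fadseed_empty_mask")
  }
  n_spot <- sum(masks$spot)
  n_el <- sum(masks$elaiosome)
  idx <- which(masks$seed_body, arr.ind = TRUE) - 1L  # 0-based
  centroid <- c(row = mean(idx[, 1]), col = mean(idx[, 2]))
  bbox <- c(row0 = min(idx[, 1]), row1 = max(idx[, 1]) + 1L,
            col0 = min(idx[, 2]), col1 = max(idx[, 2]) + 1L)
  out <- list(seed_area_px = n_seed, spot_area_px = n_spot,
              spot_cover_pct = 100 * n_spot / n_seed,
              elaiosome_area_px = n_el,
              centroid = centroid, bbox = bbox, scale = scale)
  if (!is.null(scale)) {
    assert_scalar_number(scale, "scale", min = 0)
    out$seed_area <- n_seed * scale^2
    out$spot_area <- n_spot * scale^2
    out$elaiosome_area <- n_el * scale^2
  }
  structure(out, class = "seed_morphometrics")
}

#' @export
print.seed_morphometrics <- function(x, ...) {
  cat(sprintf(
    "<seed_morphometrics: seed %d px, spots %d px (%.1f%% cover), elaiosome %d px>\n",
    x$seed_area_px, x$spot_area_px, x$spot_cover_pct, x$elaiosome_area_px))
  invisible(x)
}

#' Render segmentation layers as a four-panel composite
#'
#' Tiles the original image (top-left), the spot overlay in green
#' (top-right), the elaiosome overlay in red (bottom-left) and the combined
#' overlay (bottom-right) into one 2x2 raster.
#'
#' @param image The source image (array or `seed_image`).
#' @param masks The corresponding [mask_set()].
#' @return A (2 height) x (2 width) x 3 array in \[0, 1\].
#' @export
render_layers <- function(image, masks) {
  px <- image_pixels(image)
  stopifnot(inherits(masks, "mask_set"))
  if (!identical(dim(px)[1:2], dim(masks$seed_body))) {
    stop_fadseed("image and mask dimensions differ", "fadseed_shape_mismatch")
  }
  paint <- function(base, mask, color) {
    for (ch in 1:3) {
      plane <- base[, , ch]
      plane[mask] <- color[ch]
      base[, , ch] <- plane
    }
    base
  }
  green <- c(0, 0.8, 0); red <- c(0.9, 0, 0)
  spot_panel <- paint(px, masks$spot, green)
  el_panel <- paint(px, masks$elaiosome, red)
  both <- paint(spot_panel, masks$elaiosome, red)
  h <- dim(px)[1]; w <- dim(px)[2]
  out <- array(0, dim = c(2 * h, 2 * w, 3))
  out[1:h, 1:w, ] <- px
  out[1:h, w + 1:w, ] <- spot_panel
  out[h + 1:h, 1:w, ] <- el_panel
  out[h + 1:h, w + 1:w, ] <- both
  out
}

#' Segment and measure every image in a directory
#'
#' Runs [segment_seed()] and [measure_seed()] on each PNG in a directory and
#' returns one row per successfully processed image. Failures are logged
#' (one message per file) and reported in the `failures` attribute, never
#' silently dropped.
#'
#' @param dir Directory containing PNG seed photographs.
#' @param config A [seg_config()].
#' @param scale Optional physical scale passed to [measure_seed()].
#' @param pattern Filename regexp of images to process.
#' @return A tibble with columns source, seed_area_px, spot_area_px,
#'   spot_cover_pct, elaiosome_area_px, centroid_row, centroid_col, and an
#'   attribute `failures` (tibble: source, error).
#' @export
batch_measure <- function(dir, config = seg_config(), scale = NULL,
                          pattern = "\\.png$") {
  if (!dir.exists(dir)) {
    stop_fadseed(sprintf("directory not found: %s", dir), "fadseed_io_error")
  }
  files <- sort(list.files(dir, pattern = pattern, full.names = TRUE))
  if (length(files) == 0L) {
    stop_fadseed(sprintf("no images matching '%s' in %s", pattern, dir),
                 "fadseed_io_error")
  }
  rows <- list(); fails <- list()
  for (f in files) {
    res <- tryCatch({
      img <- read_seed_image(f, scale = scale)
      m <- measure_seed(segment_seed(img, config), scale = scale)
      tibble::tibble(source = basename(f),
                     seed_area_px = m$seed_area_px,
                     spot_area_px = m$spot_area_px,
                     spot_cover_pct = m$spot_cover_pct,
                     elaiosome_area_px = m$elaiosome_area_px,
                     centroid_row = m$centroid[["row"]],
                     centroid_col = m$centroid[["col"]])
    }, error = function(e) e)
    if (inherits(res, "error")) {
      message(sprintf("batch_measure: %s failed: %s",
                      basename(f), conditionMessage(res)))
      fails[[length(fails) + 1L]] <- tibble::tibble(
        source = basename(f), error = conditionMessage(res))
    } else {
      rows[[length(rows) + 1L]] <- res
    }
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "failures") <- dplyr::bind_rows(fails)
  out
}
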