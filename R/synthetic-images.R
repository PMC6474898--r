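#' Parameters for the synthetic seed-image generator
#'
#' Describes one rendered seed photograph: an elliptical seed body on a
#' lighter background, dark pigmentation spots covering a target fraction of
#' the body, and a pale, hue-shifted (yellowish) elaiosome disc at one pole
#' of the major axis. Spots are drawn by thresholding a smoothed Gaussian
#' noise field inside the body at the empirical quantile matching the target
#' cover, which yields a mottled texture together with exact ground truth.
#'
#' @param width,height Image size in pixels.
#' @param axis_major,axis_minor Seed ellipse semi-axes in pixels.
#' @param theta Ellipse orientation in degrees (counter-clockwise from the
#'   image x-axis).
#' @param background Background gray shade in \[0, 1\].
#' @param seed_shade Seed-coat base shade in \[0, 1\] (darker than background).
#' @param spot_shade Pigmentation-spot shade in \[0, 1\] (darker than coat).
#' @param spot_cover Target spot cover as a fraction of seed-body area, in
#'   \[0, 0.5\].
#' @param granularity Characteristic spot blob diameter in pixels; the noise
#'   field is smoothed with a Gaussian of sigma `granularity / 2`.
#' @param elaiosome_area Nominal elaiosome disc area in pixels; the rendered
#'   appendage is the part of the disc outside the seed body.
#' @param elaiosome_color Length-3 RGB colour of the elaiosome.
#' @param noise_sd Additive per-channel Gaussian noise s.d.
#' @param seed Integer RNG seed; the generator is a pure function of its
#'   parameters including this seed.
#' @return An object of class `image_gen_params`.
#' @export
image_gen_params <- function(width = 200L, height = 200L,
                             axis_major = 60, axis_minor = 38,
                             theta = 0,
                             background = 0.75, seed_shade = 0.45,
                             spot_shade = 0.15,
                             spot_cover = 0.30, granularity = 8,
                             elaiosome_area = 600,
                             elaiosome_color = c(0.88, 0.82, 0.46),
                             noise_sd = 0.02, seed = 1L) {
  assert_scalar_number(width, "width", min = 8)
  assert_scalar_number(height, "height", min = 8)
  assert_scalar_number(axis_major, "axis_major", min = 1)
  assert_scalar_number(axis_minor, "axis_minor", min = 1)
  assert_scalar_number(spot_cover, "spot_cover", min = 0, max = 0.5)
  assert_scalar_number(granularity, "granularity", min = 1)
  assert_scalar_number(elaiosome_area, "elaiosome_area", min = 0)
  assert_scalar_number(noise_sd, "noise_sd", min = 0)
  assert_scalar_number(seed, "seed")
  if (axis_minor > axis_major) stop_fadseed(
    "`axis_minor` must not exceed `axis_major`", "fadseed_invalid_params")
  r_e <- sqrt(elaiosome_area / pi)
  # the ellipse plus the elaiosome disc must fit inside the frame
  if (axis_major + 2 * r_e + 2 > min(width, height) / 2) {
    stop_fadseed(sprintf(
      "ellipse (semi-major %.0f px) plus elaiosome does not fit inside a %d x %d image",
      axis_major, as.integer(width), as.integer(height)),
      "fadseed_ellipse_too_large")
  }
  structure(list(
    width = as.integer(width), height = as.integer(height),
    axis_major = axis_major, axis_minor = axis_minor, theta = theta,
    background = background, seed_shade = seed_shade, spot_shade = spot_shade,
    spot_cover = spot_cover, granularity = granularity,
    elaiosome_area = elaiosome_area, elaiosome_color = elaiosome_color,
    noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "image_gen_params")
}

#' Binary mask layers of a segmented (or synthetic) seed image
#'
#' Holds the three layers of a seed photograph: seed body, pigmentation
#' spots and elaiosome. Invariants enforced at construction: all masks share
#' one shape, spots lie inside the seed body, and the elaiosome is disjoint
#' from the seed body.
#'
#' @param seed_body,spot,elaiosome Logical matrices of identical dimension.
#' @return An object of class `mask_set`.
#' @export
mask_set <- function(seed_body, spot, elaiosome) {
  for (m in list(seed_body, spot, elaiosome)) {
    if (!is.matrix(m) || !is.logical(m)) {
      stop_fadseed("masks must be logical matrices", "fadseed_invalid_mask")
    }
  }
  if (!identical(dim(seed_body), dim(spot)) ||
      !identical(dim(seed_body), dim(elaiosome))) {
    stop_fadseed("mask dimensions differ", "fadseed_invalid_mask")
  }
  if (any(spot & !seed_body)) {
    stop_fadseed("spot mask must be contained in the seed-body mask",
                 "fadseed_invalid_mask")
  }
  if (any(elaiosome & seed_body)) {
    stop_fadseed("elaiosome mask must be disjoint from the seed-body mask",
                 "fadseed_invalid_mask")
  }
  structure(list(seed_body = seed_body, spot = spot, elaiosome = elaiosome),
            class = "mask_set")
}

#' @export
print.mask_set <- function(x, ...) {
  cat(sprintf("<mask_set %d x %d: seed %d px, spots %d px, elaiosome %d px>\n",
              nrow(x$seed_body), ncol(x$seed_body),
              sum(x$seed_body), sum(x$spot), sum(x$elaiosome)))
  invisible(x)
}

# rotated-ellipse membership on the pixel grid (0-based centers)
ellipse_mask <- function(width, height, cx, cy, a, b, theta_deg) {
  th <- theta_deg * pi / 180
  x <- matrix(rep(seq_len(width) - 1, each = height), nrow = height) - cx
  y <- matrix(rep(seq_len(height) - 1, times = width), nrow = height) - cy
  u <- (x * cos(th) + y * sin(th)) / a
  v <- (-x * sin(th) + y * cos(th)) / b
  u^2 + v^2 <= 1
}

disc_mask <- function(width, height, cx, cy, r) {
  x <- matrix(rep(seq_len(width) - 1, each = height), nrow = height) - cx
  y <- matrix(rep(seq_len(height) - 1, times = width), nrow = height) - cy
  x^2 + y^2 <= r^2
}

#' Generate a synthetic seed photograph with ground-truth masks
#'
#' Renders an elliptical seed body with mottled dark spots and a pale
#' elaiosome at one pole, plus additive Gaussian noise, and returns the image
#' together with the exact truth masks used to render it. The spot mask is
#' the smoothed noise field inside the body thresholded at the empirical
#' quantile equal to the target cover, so the realized cover matches the
#' target to within one pixel's worth of quantile rounding (well under one
#' percentage point at default sizes). Deterministic: the same parameters
#' (including `seed`) give bit-identical output.
#'
#' @param params An [image_gen_params()] object.
#' @return A list of class `synthetic_seed_image` with elements `image`
#'   (height x width x 3 array in \[0, 1\]), `masks` (a [mask_set()]) and
#'   `params`.
#' @export
generate_seed_image <- function(params) {
  stopifnot(inherits(params, "image_gen_params"))
  p <- params
  w <- p$width; h <- p$height
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  seed_body <- ellipse_mask(w, h, cx, cy, p$axis_major, p$axis_minor, p$theta)

  out <- withr::with_seed(p$seed, {
    # spot texture: smoothed Gaussian field, quantile-thresholded in-body
    field <- matrix(rnorm(h * w), nrow = h)
    field <- matrix(as.numeric(EBImage::gblur(EBImage::Image(field),
                                              sigma = p$granularity / 2)),
                    nrow = h)
    spot <- matrix(FALSE, h, w)
    if (p$spot_cover > 0) {
      vals <- field[seed_body]
      thr <- stats::quantile(vals, p$spot_cover, type = 1, names = FALSE)
      spot <- seed_body & (field <= thr)
    }

    # elaiosome: disc straddling the pole of the major axis, kept outside
    elaiosome <- matrix(FALSE, h, w)
    if (p$elaiosome_area > 0) {
      r_e <- sqrt(p$elaiosome_area / pi)
      th <- p$theta * pi / 180
      ex <- cx + (p$axis_major + 0.8 * r_e) * cos(th)
      ey <- cy + (p$axis_major + 0.8 * r_e) * sin(th)
      elaiosome <- disc_mask(w, h, ex, ey, r_e) & !seed_body
    }

    gray <- matrix(p$background, h, w)
    gray[seed_body] <- p$seed_shade
    gray[spot] <- p$spot_shade
    img <- array(gray, dim = c(h, w, 3))
    for (ch in 1:3) {
      plane <- img[, , ch]
      plane[elaiosome] <- p$elaiosome_color[ch]
      img[, , ch] <- plane
    }
    img <- clip01(img + array(rnorm(h * w * 3, sd = p$noise_sd),
                              dim = c(h, w, 3)))
    list(image = img, spot = spot, elaiosome = elaiosome)
  })

  structure(list(
    image = out$image,
    masks = mask_set(seed_body, out$spot, out$elaiosome),
    params = p
  ), class = "synthetic_seed_image")
}

#' Write an image or mask as PNG
#'
#' Images are written as 8-bit RGB PNG; masks as single-channel 0/255 PNG.
#'
#' @param x A height x width x 3 array in \[0, 1\], a `synthetic_seed_image`,
#'   or (for `write_mask_png`) a logical matrix.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(x, path) {
  if (inherits(x, "synthetic_seed_image")) x <- x$image
  stopifnot(is.array(x), length(dim(x)) == 3L)
  png::writePNG(clip01(x), path)
  invisible(path)
}

#' @rdname write_image_png
#' @export
write_mask_png <- function(x, path) {
  stopifnot(is.logical(x), is.matrix(x))
  png::writePNG(x * 1.0, path)
  invisible(path)
}

#' Read a seed photograph from disk
#'
#' Reads PNG (via the png package) or TIFF-free formats are not needed here;
#' grayscale and RGBA images are promoted/truncated to 3-channel RGB.
#'
#' @param path Path to a PNG file.
#' @param scale Optional physical scale (length per pixel), attached as an
#'   attribute and used by [measure_seed()].
#' @return A `seed_image`: height x width x 3 array with attributes
#'   `source` and `scale`.
#' @export
read_seed_image <- function(path, scale = NULL) {
  if (!file.exists(path)) {
    stop_fadseed(sprintf("image file not found: %s", path), "fadseed_io_error")
  }
  px <- png::readPNG(path)
  as_seed_image(px, source = path, scale = scale)
}

#' @rdname read_seed_image
#' @param px A numeric array (height x width \[x channels\]) in \[0, 1\].
#' @param source Identifier recorded with the image.
#' @export
as_seed_image <- function(px, source = NA_character_, scale = NULL) {
  if (inherits(px, "synthetic_seed_image")) px <- px$image
  if (is.matrix(px)) px <- array(rep(px, 3L), dim = c(dim(px), 3L))
  if (!is.array(px) || length(dim(px)) != 3L || dim(px)[3] < 3L) {
    stop_fadseed("seed image must have 3 colour channels", "fadseed_io_error")
  }
  px <- px[, , 1:3, drop = FALSE]
  structure(px, class = "seed_image", source = source, scale = scale)
}
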