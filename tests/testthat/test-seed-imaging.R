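test_that("segmentation recovers cover and masks on synthetic seeds", {
  for (i in 1:8) {
    cv <- 0.05 + 0.40 * (i - 1) / 7
    sim <- generate_seed_image(image_gen_params(spot_cover = cv,
                                                theta = 20 * i, seed = 50 + i))
    masks <- segment_seed(sim$image)
    truth <- sim$masks
    rec <- measure_seed(masks)$spot_cover_pct
    expect_lt(abs(rec - oracle_cover_pct(truth)), 2)
    iou <- sum(masks$spot & truth$spot) / sum(masks$spot | truth$spot)
    expect_gte(iou, 0.90)
    body_iou <- sum(masks$seed_body & truth$seed_body) /
      sum(masks$seed_body | truth$seed_body)
    expect_gte(body_iou, 0.90)
  }
})

test_that("segmentation handles spotless seeds and blank images", {
  sim <- generate_seed_image(image_gen_params(spot_cover = 0, seed = 21))
  masks <- segment_seed(sim$image)
  expect_equal(sum(masks$spot), 0)
  blank <- array(0.75, dim = c(120, 120, 3)) +
    array(withr::with_seed(1, rnorm(120 * 120 * 3, sd = 0.02)),
          dim = c(120, 120, 3))
  expect_error(segment_seed(blank), "no seed detected",
               class = "fadseed_no_seed")
})

test_that("recovered cover is monotone in the target cover", {
  # identical noise realization, only the target differs
  rec <- vapply(c(0.10, 0.20, 0.30, 0.40), function(cv) {
    sim <- generate_seed_image(image_gen_params(spot_cover = cv, seed = 77))
    measure_seed(segment_seed(sim$image))$spot_cover_pct
  }, numeric(1))
  expect_true(all(diff(rec) > 0))
})

test_that("measure_seed implements the cover definition and matches pixel counts", {
  seedm <- matrix(FALSE, 20, 20); seedm[5:14, 5:14] <- TRUE   # 100 px
  spotm <- matrix(FALSE, 20, 20); spotm[5:9, 5:10] <- TRUE    # 30 px
  m <- measure_seed(mask_set(seedm, spotm, matrix(FALSE, 20, 20)))
  expect_equal(m$spot_cover_pct, 30)
  expect_equal(m$seed_area_px, 100)
  m0 <- measure_seed(mask_set(seedm, matrix(FALSE, 20, 20),
                              matrix(FALSE, 20, 20)))
  expect_equal(m0$spot_cover_pct, 0)
  # bounding box is half-open, 0-based
  expect_equal(unname(m$bbox), c(4, 14, 4, 14))
  # physical scale converts areas by scale^2
  ms <- measure_seed(mask_set(seedm, spotm, matrix(FALSE, 20, 20)), scale = 2)
  expect_equal(ms$seed_area, 400)
  # generator truth masks measure to the generator's own pixel counts
  sim <- generate_seed_image(image_gen_params(spot_cover = 0.25, seed = 31))
  mt <- measure_seed(sim$masks)
  expect_identical(mt$spot_area_px, sum(sim$masks$spot))
  expect_equal(mt$spot_cover_pct, oracle_cover_pct(sim$masks))
  expect_error(measure_seed(mask_set(matrix(FALSE, 4, 4), matrix(FALSE, 4, 4),
                                     matrix(FALSE, 4, 4))),
               class = "fadseed_empty_mask")
})

test_that("render_layers tiles 2x2 and leaves overlay panels untouched for empty masks", {
  sim <- generate_seed_image(image_gen_params(seed = 12))
  h <- dim(sim$image)[1]; w <- dim(sim$image)[2]
  empty <- mask_set(sim$masks$seed_body,
                    matrix(FALSE, h, w), matrix(FALSE, h, w))
  comp <- render_layers(sim$image, empty)
  expect_equal(dim(comp), c(2 * h, 2 * w, 3))
  expect_equal(comp[1:h, w + 1:w, ], unclass(sim$image), ignore_attr = TRUE)
  expect_equal(comp[h + 1:h, 1:w, ], unclass(sim$image), ignore_attr = TRUE)
  # full-seed spot mask paints the whole body green in the overlay panel
  full <- mask_set(sim$masks$seed_body, sim$masks$seed_body,
                   matrix(FALSE, h, w))
  comp2 <- render_layers(sim$image, full)
  overlay_g <- comp2[1:h, w + 1:w, 2]
  expect_true(all(overlay_g[sim$masks$seed_body] == 0.8))
  expect_error(render_layers(sim$image[1:50, 1:50, ], empty),
               class = "fadseed_shape_mismatch")
})

test_that("segmenting the composite's original panel reproduces the masks", {
  sim <- generate_seed_image(image_gen_params(spot_cover = 0.3, seed = 13))
  masks <- segment_seed(sim$image)
  comp <- render_layers(sim$image, masks)
  h <- dim(sim$image)[1]; w <- dim(sim$image)[2]
  masks2 <- segment_seed(comp[1:h, 1:w, ])
  expect_identical(masks2$seed_body, masks$seed_body)
  expect_identical(masks2$spot, masks$spot)
})

test_that("pixel-doubling scales areas by 4 and moves cover by less than a point", {
  sim <- generate_seed_image(image_gen_params(spot_cover = 0.3, seed = 14))
  m1 <- measure_seed(segment_seed(sim$image))
  big <- sim$image[rep(seq_len(dim(sim$image)[1]), each = 2),
                   rep(seq_len(dim(sim$image)[2]), each = 2), ]
  m2 <- measure_seed(segment_seed(big))
  expect_lt(abs(m2$seed_area_px / m1$seed_area_px - 4), 0.2)
  expect_lt(abs(m2$spot_cover_pct - m1$spot_cover_pct), 1)
})

test_that("batch_measure returns one row per readable image and logs failures", {
  dir <- withr::local_tempdir()
  for (i in 1:5) {
    sim <- generate_seed_image(image_gen_params(spot_cover = 0.1 + 0.05 * i,
                                                seed = 200 + i))
    write_image_png(sim, file.path(dir, sprintf("seed_%02d.png", i)))
  }
  writeLines("not a png", file.path(dir, "corrupt.png"))
  tab <- suppressMessages(batch_measure(dir))
  expect_equal(nrow(tab), 5)
  fails <- attr(tab, "failures")
  expect_equal(nrow(fails), 1)
  expect_equal(fails$source, "corrupt.png")
  tab2 <- suppressMessages(batch_measure(dir))
  expect_equal(tab, tab2, ignore_attr = TRUE)
  expect_error(batch_measure(withr::local_tempdir()), class = "fadseed_io_error")
})
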