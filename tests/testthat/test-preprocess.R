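# Image-conditioning chain

test_that("to_8bit rescales the display range linearly", {
  img <- channel_image(matrix(c(0, 65535, 65535, 0), 2, 2), "DAPI")
  expect_equal(sort(unique(as.vector(to_8bit(img)$pixels))), c(0, 255))
  # hand-computed linear map with rounding half up
  img <- channel_image(matrix(c(100, 300, 500, 100), 2, 2), "DAPI")
  out <- to_8bit(img)$pixels
  expect_equal(sort(unique(as.vector(out))), c(0, 128, 255))
  # constant image: zero dynamic range maps to zero
  expect_true(all(to_8bit(channel_image(matrix(500, 4, 4), "O4"))$pixels
                  == 0))
  expect_error(to_8bit(matrix(numeric(0), 0, 0)), "empty|non-empty")
})

test_that("preprocessing preserves shape and the [0, 255] range", {
  set.seed(1)
  img <- channel_image(matrix(runif(64 * 48, 0, 255), 64, 48), "O4")
  for (f in list(function(x) to_8bit(x),
                 function(x) pseudo_flat_field(x, 16),
                 function(x) median_smooth(x, 2),
                 function(x) subtract_background_paraboloid(x, 20),
                 function(x) enhance_contrast(x, 0.01))) {
    out <- f(img)
    expect_equal(dim(out$pixels), c(64L, 48L))
    expect_true(all(out$pixels >= 0 & out$pixels <= 255))
  }
})

test_that("pseudo-flat-field is a fixed point on uniform images and keeps the mean", {
  img <- channel_image(matrix(120, 40, 40), "MBP")
  out <- pseudo_flat_field(img, 10)
  expect_equal(out$pixels, img$pixels, tolerance = 1e-6)
  set.seed(2)
  img <- channel_image(matrix(runif(60 * 60, 20, 200), 60, 60), "MBP")
  out <- pseudo_flat_field(img, 20)
  expect_lt(abs(mean(out$pixels) - mean(img$pixels)), 1)
})

test_that("pseudo-flat-field strongly reduces a linear illumination gradient", {
  n <- 120
  gain <- matrix(rep(seq(0.6, 1.4, length.out = n), each = n), n, n)
  img <- channel_image(100 * gain, "MBP")
  out <- pseudo_flat_field(img, n / 3)
  cv <- function(m) sd(m) / mean(m)
  expect_gt(cv(img$pixels) / cv(out$pixels), 5)
})

test_that("median filter handles constants, impulses and the 3x3 oracle", {
  img <- channel_image(matrix(7, 20, 20), "DAPI")
  expect_equal(median_smooth(img, 2)$pixels, img$pixels)
  hot <- matrix(0, 21, 21); hot[11, 11] <- 255
  out <- median_smooth(channel_image(hot, "DAPI"), 1)
  expect_equal(max(out$pixels), 0)
  # centre of {0,...,255,...0}: median over the radius-1 disc is 0
  m <- matrix(0, 3, 3); m[2, 2] <- 255
  expect_equal(median_smooth(channel_image(m, "DAPI"), 1)$pixels[2, 2], 0)
  expect_error(median_smooth(img, 0.5), ">= 1")
})

test_that("paraboloid background subtraction removes smooth backgrounds", {
  z <- channel_image(matrix(0, 50, 50), "O4")
  expect_true(all(subtract_background_paraboloid(z, 20)$pixels == 0))
  cimg <- channel_image(matrix(63, 50, 50), "O4")
  expect_lt(max(subtract_background_paraboloid(cimg, 20)$pixels), 1)
})

test_that("paraboloid subtraction keeps narrow ridges on a dome background", {
  n <- 128
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  dome <- 80 * exp(-((yy - 64)^2 + (xx - 64)^2) / (2 * 45^2))
  ridge <- matrix(0, n, n)
  for (j in 1:n) ridge[, j] <- pmax(ridge[, j],
                                    100 * exp(-((yy[, j] - 40)^2) / (2 * 1.5^2)))
  img <- channel_image(dome + ridge, "O4")
  # radius chosen so the structuring element is steeper than the dome
  # (2r < 2*45^2/80) but far wider than the 3-px ridges
  out <- subtract_background_paraboloid(img, 20)$pixels
  # ridge peak height preserved within 15%
  peak_in <- max(ridge)
  peak_out <- max(out[38:42, 40:90] - out[30, 40:90])
  expect_gt(peak_out, 0.85 * peak_in)
  # dome removed within 10% of its amplitude away from the ridge
  expect_lt(max(out[55:75, 55:75]), 0.1 * 80 + 1)
})

test_that("contrast enhancement maps the saturation quantiles to 0/255", {
  # already spanning [0,255], zero saturation: unchanged
  set.seed(3)
  px <- matrix(sample(0:255, 400, TRUE), 20, 20)
  px[1] <- 0; px[2] <- 255
  img <- channel_image(px, "DAPI")
  expect_equal(enhance_contrast(img, 0)$pixels, px)
  # uniform on [50, 200]: endpoints map to 0 and 255
  px <- matrix(seq(50, 200, length.out = 100), 10, 10)
  out <- enhance_contrast(channel_image(px, "O4"), 0)$pixels
  expect_equal(min(out), 0)
  expect_equal(max(out), 255)
  # rank-enumerated quantile oracle: pixels below the 1st and above the
  # 99th percentile clip to 0/255
  set.seed(4)
  v <- sort(runif(1000, 0, 255))
  img <- channel_image(matrix(v, 25, 40), "O4")
  out <- enhance_contrast(img, 0.02)$pixels
  lo <- quantile(v, 0.01, type = 7); hi <- quantile(v, 0.99, type = 7)
  expect_true(all(out[img$pixels < lo] == 0))
  expect_true(all(out[img$pixels > hi] == 255))
  expect_true(all(out[img$pixels > lo & img$pixels < hi] > 0 &
                    out[img$pixels > lo & img$pixels < hi] < 255))
  expect_warning(enhance_contrast(channel_image(matrix(9, 5, 5), "O4")),
                 "constant")
  expect_error(enhance_contrast(img, 0.6), "0.5")
})

test_that("the canonical chain applies the documented channel routing", {
  set.seed(5)
  mk <- function(ch) channel_image(matrix(runif(48 * 48, 0, 255), 48, 48),
                                   ch)
  prov <- function(img) preprocess_channel(
    img, utils::modifyList(default_config()$preprocess,
                           list(flat_field_radius = 16,
                                paraboloid_radius = 20)))$provenance
  p_mbp <- prov(mk("MBP"))
  expect_true(any(grepl("flat_field", p_mbp)))
  expect_false(any(grepl("paraboloid", p_mbp)))
  expect_false(any(grepl("enhance", p_mbp)))
  p_dapi <- prov(mk("DAPI"))
  expect_false(any(grepl("flat_field", p_dapi)))
  expect_true(any(grepl("paraboloid", p_dapi)))
  expect_true(any(grepl("enhance", p_dapi)))
  p_o4 <- prov(mk("O4"))
  expect_true(any(grepl("flat_field", p_o4)))
  expect_true(any(grepl("paraboloid", p_o4)))
  expect_true(any(grepl("enhance", p_o4)))
  # order follows the canonical chain
  expect_equal(p_o4[1], "to_8bit")
  expect_true(which(grepl("median", p_o4)) > which(grepl("flat", p_o4)))
  expect_true(which(grepl("enhance", p_o4)) > which(grepl("paraboloid",
                                                          p_o4)))
})

test_that("vignetting barely moves the downstream Huang threshold", {
  # compared on noise-free renders: the Huang fuzziness minimum sits in a
  # very flat basin, and photon/read noise alone moves the argmin by more
  # than the +-2 band even with identical illumination, masking the effect
  # this property is about (the flat-field correction undoing vignetting)
  cfg <- default_config()$preprocess
  th <- function(amp, seed) {
    p <- scene_params(image_shape = c(160, 160), n_cells = 3,
                      illumination_amplitude = amp, bleed_coefficient = 0,
                      photon_scale = Inf, read_sd = 0)
    ch <- render_channels(generate_scene(p, seed))
    huang_threshold(preprocess_channel(ch$marker, cfg), "huang2")$threshold
  }
  for (sd in 21:24)
    expect_lte(abs(th(0, sd) - th(0.3, sd)), 2)
})
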