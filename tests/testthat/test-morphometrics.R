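# Percent positive, cell size, ridge detection, skeletonization, summaries

test_that("percent_positive follows the centroid colocalization rule", {
  shp <- c(60, 60)
  mk_set <- function(blocks) {
    m <- matrix(FALSE, shp[1], shp[2])
    for (b in blocks) m[b[1]:b[2], b[3]:b[4]] <- TRUE
    roi_set_from_mask(m)
  }
  dapi <- mk_set(list(c(5, 9, 5, 9), c(20, 24, 20, 24), c(40, 44, 40, 44)))
  # no marker ROIs -> 0
  none <- structure(list(), shape = c(60L, 60L), class = "roi_set")
  expect_equal(percent_positive(none, dapi), 0)
  # all DAPI centroids covered by distinct marker ROIs -> 100
  marker <- mk_set(list(c(3, 12, 3, 12), c(18, 27, 18, 27),
                        c(38, 47, 38, 47), c(52, 56, 52, 56)))
  expect_equal(percent_positive(marker, dapi), 100)
  # one of three covered
  marker1 <- mk_set(list(c(3, 12, 3, 12)))
  expect_equal(percent_positive(marker1, dapi), 100 / 3)
  # no DAPI -> NA with message
  expect_message(res <- percent_positive(marker, none), "NA")
  expect_true(is.na(res))
})

test_that("truth percent positive is exact by construction (6 of 10)", {
  p <- scene_params(image_shape = c(320, 320), n_cells = 10,
                    coloc_fraction = 0.6, n_free_nuclei = 4,
                    min_cell_spacing_px = 50)
  sc <- generate_scene(p, seed = 12)
  expect_equal(sc$truth$n_colocalized, 6)
  expect_equal(sc$truth$n_nuclei, 10)
  expect_equal(sc$truth$percent_positive, 60)
})

test_that("average_cell_size is total area over cell count", {
  m <- matrix(FALSE, 40, 40); m[1:30, 1:30] <- TRUE
  expect_equal(average_cell_size(binary_mask(m), 9), 100)
  expect_equal(average_cell_size(binary_mask(matrix(FALSE, 5, 5)), 5), 0)
  expect_message(res <- average_cell_size(binary_mask(m), 0), "NA")
  expect_true(is.na(res))
  expect_equal(average_cell_size(binary_mask(m), 9, pixel_size_um = 2),
               400)
})

test_that("ridge detection: blank image, single line, crossing", {
  blank <- channel_image(matrix(0, 64, 64), "MBP")
  ls <- detect_ridges(blank)
  expect_length(ls$polylines, 0)
  expect_equal(nrow(ls$junction_points), 0)

  # one Gaussian-profile line, width ~3 px: exactly one polyline with
  # sub-pixel RMS < 0.5 px from the true centreline
  p1 <- cbind(seq(20, 100, length.out = 50), seq(30, 110, length.out = 50))
  img <- fixture_line_image(list(p1))
  ls <- detect_ridges(img, sigma = 1.8, high_contrast = 55)
  expect_length(ls$polylines, 1)
  pts <- ls$polylines[[1]]
  d <- abs((pts[, 1] - 20) - (pts[, 2] - 30)) / sqrt(2)
  expect_lt(sqrt(mean(d^2)), 0.5)

  # two crossing lines: a junction within 2 px of the true crossing (60,70)
  p2 <- cbind(seq(100, 20, length.out = 50), seq(30, 110, length.out = 50))
  lsx <- detect_ridges(fixture_line_image(list(p1, p2)))
  expect_gte(nrow(lsx$junction_points), 1)
  dmin <- min(sqrt((lsx$junction_points[, 1] - 60)^2 +
                     (lsx$junction_points[, 2] - 70)^2))
  expect_lt(dmin, 2)
  expect_error(detect_ridges(img, low_contrast = 60, high_contrast = 50),
               "low_contrast")
})

test_that("skeletonization: straight line, Y, filled disc", {
  m <- matrix(FALSE, 20, 60); m[10, 6:55] <- TRUE
  g <- skeletonize_mask(binary_mask(m), prune_px = 0,
                        merge_junctions_px = 0)
  expect_length(g$edges, 1)
  expect_equal(g$n_junctions, 0)
  expect_equal(g$edges[[1]]$length_px, 49)

  # Y: three 20-px arms from one point
  m <- matrix(FALSE, 64, 64)
  for (k in 0:20) {
    m[32 - k, 32] <- TRUE                      # up
    m[32 + k, 32 - k] <- TRUE                  # down-left diagonal
    m[32 + k, 32 + k] <- TRUE                  # down-right diagonal
  }
  g <- skeletonize_mask(binary_mask(m))
  expect_equal(g$n_junctions, 1)
  expect_equal(length(g$edges), 3)

  # filled disc: skeleton collapses to little more than a point
  yy <- row(matrix(0, 50, 50)); xx <- col(matrix(0, 50, 50))
  disc <- (yy - 25)^2 + (xx - 25)^2 <= 15^2
  g <- skeletonize_mask(binary_mask(disc), prune_px = 4)
  expect_equal(g$n_junctions, 0)
  tot <- sum(vapply(g$edges, `[[`, numeric(1), "length_px"))
  expect_lt(tot, 2 * 30)  # much less than diameter x 2
  # empty mask
  g <- skeletonize_mask(binary_mask(matrix(FALSE, 10, 10)))
  expect_length(g$edges, 0)
})

test_that("summarize_morphology arithmetic and missing-value contract", {
  ls <- structure(list(polylines = list(), lengths_um = c(10, 20, 30),
                       junction_points = matrix(0, 2, 2),
                       total_length_um = 60, pixel_size_um = 1),
                  class = "line_set")
  s <- summarize_morphology(ls, 4, "ridge")
  expect_equal(s$avg_branch_length, 20)
  expect_equal(s$avg_junction_number, 0.5)
  expect_false(s$flagged)
  # no branches -> flagged missing
  ls$lengths_um <- numeric()
  s <- summarize_morphology(ls, 4, "ridge")
  expect_true(is.na(s$avg_branch_length))
  expect_true(is.na(s$avg_junction_number))
  expect_true(s$flagged)
  # zero cells -> missing
  expect_message(s <- summarize_morphology(ls, 0, "ridge"), "NA")
  expect_true(s$flagged)
})

test_that("doubling pixel size doubles lengths, junction counts unchanged", {
  p1 <- cbind(seq(20, 100, length.out = 50), seq(30, 110, length.out = 50))
  p2 <- cbind(seq(100, 20, length.out = 50), seq(30, 110, length.out = 50))
  img1 <- fixture_line_image(list(p1, p2), pixel_size_um = 1)
  img2 <- fixture_line_image(list(p1, p2), pixel_size_um = 2)
  l1 <- detect_ridges(img1); l2 <- detect_ridges(img2)
  expect_equal(l2$total_length_um, 2 * l1$total_length_um)
  expect_equal(nrow(l2$junction_points), nrow(l1$junction_points))
  m <- matrix(FALSE, 20, 60); m[10, 6:55] <- TRUE
  g1 <- skeletonize_mask(binary_mask(m), 1, prune_px = 0)
  g2 <- skeletonize_mask(binary_mask(m), 2, prune_px = 0)
  expect_equal(g2$edges[[1]]$length_um, 2 * g1$edges[[1]]$length_um)
  expect_equal(g2$n_junctions, g1$n_junctions)
})

test_that("compact O4 discs recover their area through the standard chain", {
  # discs of radius 10 -> mean size within 15% of pi * 10^2 after the
  # O4 route (flat field, median, background, contrast, Huang, erode+open)
  p <- scene_params(image_shape = c(256, 256), marker = "O4", n_cells = 6,
                    soma_radius_px = c(10, 10), n_primary = c(0, 0),
                    n_free_nuclei = 0, min_cell_spacing_px = 55,
                    bleed_coefficient = 0, illumination_amplitude = 0.15)
  sc <- generate_scene(p, seed = 31)
  ch <- render_channels(sc)
  cfg <- validate_config()
  pre <- preprocess_channel(ch$marker, cfg$preprocess)
  mask <- apply_binary_ops(huang_threshold(pre, "huang")$mask,
                           c("erode", "open"))
  rois <- extract_rois(mask, 20)
  expect_equal(length(rois), 6)
  size <- average_cell_size(roi_union_mask(rois, "O4"), length(rois))
  expect_lt(abs(size - pi * 100) / (pi * 100), 0.15)
})
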