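# Thresholding, binary operations, ROI extraction, bleed-through filters

test_that("huang threshold matches the exhaustive fuzzy-entropy oracle", {
  # two-level image
  # two-level image: every cut between the levels separates them perfectly
  # (fuzziness 0); ties resolve to the lowest candidate, and the mask must
  # recover exactly the bright class
  px <- matrix(c(rep(10, 50), rep(200, 50)), 10, 10)
  img <- channel_image(px, "O4")
  res <- huang_threshold(img, "huang")
  expect_gte(res$threshold, 10)
  expect_lt(res$threshold, 200)
  expect_identical(res$mask$pixels, px == 200)
  expect_equal(res$threshold, oracle_huang(hist256(px)))
  # binary 0/255 image: mask recovers exactly the 255 pixels
  px <- matrix(0, 12, 12); px[3:6, 3:9] <- 255
  res <- huang_threshold(channel_image(px, "MBP"), "huang2")
  expect_identical(res$mask$pixels, px == 255)
  expect_error(huang_threshold(channel_image(matrix(7, 5, 5), "O4")),
               "degenerate")
})

test_that("huang and huang2 agree on random bimodal histograms", {
  n_same <- 0; maxdiff <- 0
  for (k in 1:50) {
    counts <- random_bimodal_hist(1000 + k)
    v <- rep(0:255, counts)
    img <- channel_image(matrix(v, 1), "O4")
    t1 <- huang_threshold(img, "huang")$threshold
    t2 <- huang_threshold(img, "huang2")$threshold
    if (t1 == t2) n_same <- n_same + 1
    maxdiff <- max(maxdiff, abs(t1 - t2))
  }
  expect_gte(n_same, 48)
  expect_lte(maxdiff, 2)
})

test_that("binary ops: empty mask, morphology monotonicity, unknown op", {
  empty <- binary_mask(matrix(FALSE, 20, 20))
  for (ops in list("erode", "open", "dilate", "watershed",
                   c("erode", "open", "dilate", "watershed")))
    expect_equal(sum(apply_binary_ops(empty, ops)$pixels), 0)
  yy <- row(matrix(0, 41, 41)); xx <- col(matrix(0, 41, 41))
  disc <- binary_mask((yy - 21)^2 + (xx - 21)^2 <= 10^2)
  er <- apply_binary_ops(disc, "erode")
  expect_lt(sum(er$pixels), sum(disc$pixels))
  di <- apply_binary_ops(er, "dilate")
  expect_gte(sum(di$pixels), sum(er$pixels))
  expect_error(apply_binary_ops(disc, c("erode", "sharpen")), "unknown")
  expect_error(apply_binary_ops(disc, character(0)), "non-empty")
})

test_that("watershed splits two touching discs into two components", {
  yy <- row(matrix(0, 48, 64)); xx <- col(matrix(0, 48, 64))
  m <- (yy - 24)^2 + (xx - 25)^2 <= 9^2 | (yy - 24)^2 + (xx - 39)^2 <= 9^2
  expect_equal(max(oligomorph:::cpp_label(m, 8L)), 1)  # one merged blob
  ws <- apply_binary_ops(binary_mask(m), "watershed")
  expect_equal(length(extract_rois(ws, min_area_px = 10)), 2)
})

test_that("extract_rois computes areas, solidity and respects min_area", {
  m <- matrix(FALSE, 20, 20); m[5:10, 4:12] <- TRUE
  rois <- roi_set_from_mask(m)
  expect_length(rois, 1)
  expect_equal(rois[[1]]$area_px, 6 * 9)
  expect_equal(rois[[1]]$solidity, 1.0)
  expect_equal(rois[[1]]$centroid, c(7.5, 8))
  # plus shape: solidity = 9 / hull pixel count (brute-force oracle)
  m <- matrix(FALSE, 15, 15)
  m[8, 6:10] <- TRUE; m[6:10, 8] <- TRUE
  rois <- roi_set_from_mask(m)
  pts <- which(m, arr.ind = TRUE); colnames(pts) <- NULL
  expect_equal(rois[[1]]$solidity, 9 / oracle_hull_count(pts))
  expect_equal(oracle_hull_count(pts), 13)
  # size filter: blobs of 3 and 50 px with min_area 10 -> one ROI
  m <- matrix(FALSE, 30, 30)
  m[2, 2:4] <- TRUE; m[10:19, 10:14] <- TRUE
  expect_length(extract_rois(binary_mask(m), min_area_px = 10), 1)
  expect_length(extract_rois(binary_mask(matrix(FALSE, 5, 5)), 1), 0)
  # area_um2 uses the pixel size
  rois <- extract_rois(binary_mask(m), 10, pixel_size_um = 0.5)
  expect_equal(rois[[1]]$area_um2, 50 * 0.25)
})

test_that("ROI pixel sets are disjoint and lie within the mask", {
  set.seed(8)
  m <- matrix(runif(60 * 60) > 0.7, 60, 60)
  rois <- extract_rois(binary_mask(m), min_area_px = 3)
  seen <- matrix(FALSE, 60, 60)
  for (r in rois) {
    expect_false(any(seen[r$pixels]))
    seen[r$pixels] <- TRUE
    expect_true(all(m[r$pixels]))
  }
})

test_that("solidity filter keeps < 0.7 strictly and is idempotent", {
  mk_roi <- function(sol) list(label = 1L, pixels = cbind(1, 1),
                               area_px = 1, area_um2 = 1,
                               centroid = c(1, 1), bbox = c(1, 1, 1, 1),
                               solidity = sol)
  rois <- structure(lapply(c(0.65, 0.70, 0.9999), mk_roi),
                    shape = c(5L, 5L), class = "roi_set")
  kept <- filter_by_solidity(rois)
  expect_length(kept, 1)
  expect_equal(kept[[1]]$solidity, 0.65)
  expect_equal(filter_by_solidity(kept), kept)
  # a filled disc (solidity ~ 1) is removed
  yy <- row(matrix(0, 25, 25)); xx <- col(matrix(0, 25, 25))
  disc <- roi_set_from_mask((yy - 13)^2 + (xx - 13)^2 <= 8^2)
  expect_length(filter_by_solidity(disc), 0)
})

test_that("overlap filter uses the target-area fraction with strict cut", {
  shp <- c(40, 40)
  mref <- matrix(FALSE, shp[1], shp[2]); mref[1:20, 1:20] <- TRUE
  ref <- roi_set_from_mask(mref)
  # 59% overlap kept, 60% removed (strict), 0% kept, 100% removed
  t59 <- structure(list(list(label = 1L,
                             pixels = rbind(which(mref, arr.ind = TRUE)[1:59, ],
                                            which(!mref, arr.ind = TRUE)[1:41, ]),
                             area_px = 100, area_um2 = 100,
                             centroid = c(10, 10), bbox = c(1, 1, 40, 40),
                             solidity = 0.5)),
                   shape = c(40L, 40L), class = "roi_set")
  expect_length(filter_bleedthrough(t59, ref), 1)
  expect_equal(filter_bleedthrough(t59, ref)[[1]]$overlap_fraction, 0.59)
  t60 <- t59
  t60[[1]]$pixels <- rbind(which(mref, arr.ind = TRUE)[1:60, ],
                           which(!mref, arr.ind = TRUE)[1:40, ])
  expect_length(filter_bleedthrough(t60, ref), 0)
  t0 <- t59
  t0[[1]]$pixels <- which(!mref, arr.ind = TRUE)[1:100, ]
  expect_length(filter_bleedthrough(t0, ref), 1)
  t100 <- t59
  t100[[1]]$pixels <- which(mref, arr.ind = TRUE)[1:100, ]
  expect_length(filter_bleedthrough(t100, ref), 0)
  # idempotence
  kept <- filter_bleedthrough(t59, ref)
  expect_equal(rois_to_df(filter_bleedthrough(kept, ref)),
               rois_to_df(kept))
  # shape mismatch
  bad <- structure(list(), shape = c(10L, 10L), class = "roi_set")
  expect_error(filter_bleedthrough(t59, bad), "shape")
})

test_that("huang_threshold equals the oracle on random histograms", {
  for (k in 1:30) {
    counts <- random_bimodal_hist(7000 + k)
    v <- rep(0:255, counts)
    img <- channel_image(matrix(v, 1), "MBP")
    expect_equal(huang_threshold(img, "huang")$threshold,
                 oracle_huang(counts))
  }
})
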