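# Shared fixtures and independent oracles used across test files.

# render Gaussian-profile polylines into a channel_image (truth-controlled
# ridge fixture)
fixture_line_image <- function(polys, amp = 110, s = 1.5,
                               shape = c(128, 128), channel = "MBP",
                               pixel_size_um = 1) {
  acc <- matrix(0, shape[1], shape[2])
  for (p in polys)
    acc <- oligomorph:::raster_polyline_gauss(acc, p, s, amp)
  channel_image(round(acc), channel, pixel_size_um)
}

# independent exhaustive Huang fuzzy-entropy minimiser over all candidate
# thresholds of a 256-bin histogram (ties to the lowest threshold)
oracle_huang <- function(counts) {
  g <- 0:255
  nz <- which(counts > 0) - 1L
  first <- min(nz); last <- max(nz)
  C <- last - first
  n <- sum(counts)
  best_t <- NA_integer_; best_e <- Inf
  for (t in first:(last - 1L)) {
    sel <- g <= t
    w0 <- sum(counts[sel]); w1 <- n - w0
    mu0 <- sum(counts[sel] * g[sel]) / w0
    mu1 <- sum(counts[!sel] * g[!sel]) / w1
    u <- ifelse(sel, 1 / (1 + abs(g - mu0) / C), 1 / (1 + abs(g - mu1) / C))
    sterm <- ifelse(u <= 0 | u >= 1, 0, -u * log(u) - (1 - u) * log(1 - u))
    e <- sum(counts * sterm) / n
    if (e < best_e - 1e-12) { best_e <- e; best_t <- t }
  }
  best_t
}

# histogram of an intensity matrix, as the package builds it
hist256 <- function(px) {
  v <- pmin(pmax(round(px), 0), 255)
  tabulate(as.integer(v) + 1L, nbins = 256L)
}

# brute-force count of lattice points inside/on the convex hull of a pixel
# set: for every bbox point, test membership by checking it cannot be
# separated from the hull vertices (exact integer half-plane test on every
# pair of hull points serving as an edge of the full point set's hull via
# chull)
oracle_hull_count <- function(pts) {
  pts <- unique(pts)
  if (nrow(pts) <= 2) return(nrow(pts))
  h <- grDevices::chull(pts[, 2], pts[, 1])
  V <- pts[h, , drop = FALSE]
  k <- nrow(V)
  if (k <= 2) return(nrow(pts))
  xs <- V[, 2]; ys <- V[, 1]
  sgn <- sign(sum(xs * ys[c(2:k, 1)] - xs[c(2:k, 1)] * ys))
  cnt <- 0
  for (i in min(pts[, 1]):max(pts[, 1]))
    for (j in min(pts[, 2]):max(pts[, 2])) {
      ok <- TRUE
      for (e in seq_len(k)) {
        a <- V[e, ]; b <- V[if (e == k) 1 else e + 1, ]
        cr <- (b[2] - a[2]) * (i - a[1]) - (b[1] - a[1]) * (j - a[2])
        if (sgn * cr < 0) { ok <- FALSE; break }
      }
      if (ok) cnt <- cnt + 1
    }
  cnt
}

# random bimodal 256-bin histogram (two discretised normal components)
random_bimodal_hist <- function(seed) {
  set.seed(seed)
  m1 <- runif(1, 30, 100); m2 <- runif(1, 140, 220)
  s1 <- runif(1, 5, 25); s2 <- runif(1, 5, 25)
  n1 <- sample(500:3000, 1); n2 <- sample(500:3000, 1)
  v <- c(rnorm(n1, m1, s1), rnorm(n2, m2, s2))
  hist256(matrix(v, 1))
}

# a roi_set built directly from a labelled logical matrix
roi_set_from_mask <- function(m, min_area = 1, pixel_size_um = 1) {
  extract_rois(binary_mask(m), min_area_px = min_area,
               pixel_size_um = pixel_size_um)
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))
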