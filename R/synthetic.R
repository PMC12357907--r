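# Ground-truthed synthetic scenes: DAPI nuclei, compact O4 precursors or
# branched MBP oligodendrocytes with tree-like process skeletons, DAPI
# bleed-through into the marker channel, polynomial vignetting and
# Poisson + Gaussian noise. Every quantity a downstream stage estimates
# (percent positive, branch lengths, junction counts) is recorded exactly.

#' Parameters of a synthetic two-channel scene
#'
#' Defaults describe a field of view of cultured oligodendroglia at roughly
#' 20x magnification: a 256 x 256 px field (0.6 um/px), a dozen nuclei and a
#' handful of marker-positive cells. `marker = "MBP"` produces branched cells
#' whose processes are random binary trees rasterised with a Gaussian ridge
#' profile; `marker = "O4"` produces compact cells with few short processes.
#'
#' @param image_shape integer (rows, cols), each >= 64.
#' @param n_cells number of marker-positive cells.
#' @param marker `"MBP"` or `"O4"`.
#' @param coloc_fraction fraction of cells that sit on a DAPI nucleus.
#' @param n_free_nuclei additional nuclei with no marker-positive cell.
#' @param nucleus_axes_px range of nucleus semi-axes (px).
#' @param nucleus_intensity range of nucleus peak intensities (grey levels).
#' @param min_cell_spacing_px minimum distance between soma centres
#'   (rejection-sampled; emulates sparse plating).
#' @param soma_radius_px range of soma radii (px).
#' @param soma_intensity soma peak intensity (grey levels).
#' @param process_contrast peak intensity of process ridges (grey levels).
#' @param process_width_px full width of the Gaussian ridge profile
#'   (about 2 profile standard deviations).
#' @param n_primary range of primary processes per cell.
#' @param branch_prob probability a segment end splits into two children.
#' @param max_depth maximum branching depth.
#' @param segment_length_px range of branch segment lengths (px).
#' @param branch_angle_deg range of child branch angle offsets (degrees).
#' @param bend_sd_deg within-segment bend jitter (degrees, per subsegment).
#' @param length_scale multiplier on all segment lengths (used to inject
#'   group effects on branch length).
#' @param bleed_coefficient fraction of the blurred DAPI signal leaking into
#'   the marker channel (>= 0).
#' @param bleed_blur_sigma Gaussian sigma (px) of the leakage blur.
#' @param illumination_amplitude amplitude of the low-order polynomial
#'   vignetting field (0 disables it).
#' @param photon_scale photons per grey level for Poisson shot noise
#'   (`Inf` disables shot noise).
#' @param read_sd Gaussian read-noise standard deviation (grey levels).
#' @param pixel_size_um physical pixel size (um/px); free parameter, the
#'   source protocol does not pin a magnification.
#' @param bit_depth bit depth images are quantised to when rendered.
#' @return a named list of validated parameters.
#' @export
scene_params <- function(image_shape = c(256, 256),
                         n_cells = 7,
                         marker = c("MBP", "O4"),
                         coloc_fraction = 0.85,
                         n_free_nuclei = 5,
                         nucleus_axes_px = c(4, 7),
                         nucleus_intensity = c(150, 220),
                         min_cell_spacing_px = 65,
                         soma_radius_px = NULL,
                         soma_intensity = 115,
                         process_contrast = 110,
                         process_width_px = 3,
                         n_primary = NULL,
                         branch_prob = NULL,
                         max_depth = NULL,
                         segment_length_px = NULL,
                         branch_angle_deg = c(25, 55),
                         bend_sd_deg = 7,
                         length_scale = 1,
                         bleed_coefficient = 0.3,
                         bleed_blur_sigma = 2,
                         illumination_amplitude = 0.25,
                         photon_scale = 2,
                         read_sd = 2,
                         pixel_size_um = 0.6,
                         bit_depth = 8) {
  marker <- match.arg(marker)
  if (length(image_shape) != 2 || any(image_shape < 64))
    stop("image_shape must be two dimensions, each >= 64", call. = FALSE)
  if (n_cells < 0 || n_free_nuclei < 0)
    stop("counts must be >= 0", call. = FALSE)
  if (bleed_coefficient < 0)
    stop("bleed_coefficient must be >= 0", call. = FALSE)
  # marker-dependent morphology defaults
  if (marker == "MBP") {
    if (is.null(soma_radius_px)) soma_radius_px <- c(2.5, 3.5)
    if (is.null(n_primary)) n_primary <- c(3, 4)
    if (is.null(branch_prob)) branch_prob <- 0.5
    if (is.null(max_depth)) max_depth <- 2
    if (is.null(segment_length_px)) segment_length_px <- c(12, 22)
  } else {
    if (is.null(soma_radius_px)) soma_radius_px <- c(6, 9)
    if (is.null(n_primary)) n_primary <- c(1, 3)
    if (is.null(branch_prob)) branch_prob <- 0.1
    if (is.null(max_depth)) max_depth <- 1
    if (is.null(segment_length_px)) segment_length_px <- c(6, 14)
  }
  as.list(environment())
}

#' Scene parameters for low-noise ground-truth benchmarking
#'
#' Same morphology as [scene_params()] but near-noiseless imaging: flat
#' illumination, no bleed-through, high photon budget. Used when measuring
#' how faithfully the morphometric backends recover known truth.
#'
#' @param ... overrides passed to [scene_params()].
#' @return a parameter list.
#' @export
scene_params_noise_light <- function(...) {
  defaults <- list(bleed_coefficient = 0, illumination_amplitude = 0,
                   photon_scale = 50, read_sd = 1)
  args <- utils::modifyList(defaults, list(...))
  do.call(scene_params, args)
}

deg2rad <- function(d) d * pi / 180

# uniform integer in [lo, hi] (safe against R's sample(n, 1) scalar rule)
sample_int_range <- function(lo, hi) {
  lo + sample.int(hi - lo + 1L, 1L) - 1L
}

# one curved segment as a polyline from p0 at angle theta; growth stops at
# the safe margin (no direction reversal — hairpin segments would put a
# branch's own legs closer than any junction radius)
grow_segment <- function(p0, theta, len, bend_sd, shape, margin = 4) {
  nsub <- max(2L, ceiling(len / 8))
  step <- len / nsub
  pts <- matrix(0, nsub + 1, 2)
  pts[1, ] <- p0
  th <- theta
  n_ok <- 1L
  for (k in seq_len(nsub)) {
    nxt <- pts[k, ] + step * c(sin(th), cos(th))
    if (nxt[1] < margin || nxt[1] > shape[1] - margin ||
        nxt[2] < margin || nxt[2] > shape[2] - margin) break
    pts[k + 1, ] <- nxt
    n_ok <- k + 1L
    th <- th + stats::rnorm(1, 0, deg2rad(bend_sd))
  }
  pts[seq_len(n_ok), , drop = FALSE]
}

polyline_length <- function(p) {
  if (nrow(p) < 2) return(0)
  sum(sqrt(rowSums((p[-1, , drop = FALSE] - p[-nrow(p), , drop = FALSE])^2)))
}

# resample a polyline at roughly `step`-px spacing (for collision tests)
densify_polyline <- function(p, step = 2) {
  out <- list(p[1, , drop = FALSE])
  for (k in seq_len(nrow(p) - 1)) {
    a <- p[k, ]; b <- p[k + 1, ]
    L <- sqrt(sum((b - a)^2))
    n <- max(1L, ceiling(L / step))
    t <- seq_len(n) / n
    out[[k + 1]] <- cbind(a[1] + t * (b[1] - a[1]), a[2] + t * (b[2] - a[2]))
  }
  do.call(rbind, out)
}

# random binary process tree rooted at `center`. Segments that would come
# closer than `clearance` px to already-placed structure (this or earlier
# cells) are re-drawn at a new angle and finally skipped, so the rendered
# scene contains no process crossings the truth records would not know
# about. A split is committed only if both children can be placed. Returns
# nodes (y, x), edges (from, to, polyline, length_px) and the updated
# occupancy point set.
grow_tree <- function(center, params, occ = NULL, clearance = 8) {
  p <- params
  nodes <- list(center)
  edges <- list()
  place_segment <- function(from_pt, theta, occ_now) {
    for (try in 1:8) {
      len <- stats::runif(1, p$segment_length_px[1],
                          p$segment_length_px[2]) * p$length_scale
      poly <- grow_segment(from_pt, theta, len, p$bend_sd_deg,
                           p$image_shape)
      if (nrow(poly) < 2 || polyline_length(poly) < 0.7 * len) {
        # truncated at the border: re-draw the direction
        theta <- theta + stats::rnorm(1, 0, deg2rad(30))
        next
      }
      dense <- densify_polyline(poly)
      dfrom <- sqrt(rowSums(sweep(dense, 2, from_pt)^2))
      # exclude a start neighbourhood scaled so freshly split siblings (>=
      # 50 degrees apart) are not rejected against each other
      test <- dense[dfrom > 1.3 * clearance, , drop = FALSE]
      ok <- is.null(occ_now) || nrow(test) == 0 || {
        dd <- outer(test[, 1], occ_now[, 1], "-")^2 +
          outer(test[, 2], occ_now[, 2], "-")^2
        min(dd) >= clearance^2
      }
      if (ok) return(list(poly = poly, dense = dense))
      theta <- theta + stats::rnorm(1, 0, deg2rad(30))
    }
    NULL
  }
  end_angle <- function(poly)
    atan2(poly[nrow(poly), 1] - poly[nrow(poly) - 1, 1],
          poly[nrow(poly), 2] - poly[nrow(poly) - 1, 2])
  add_edge <- function(from, seg) {
    nodes[[length(nodes) + 1]] <<- seg$poly[nrow(seg$poly), ]
    edges[[length(edges) + 1]] <<- list(
      from = from, to = length(nodes), poly = seg$poly,
      length_px = polyline_length(seg$poly))
    occ <<- rbind(occ, seg$dense)
    length(nodes)
  }
  npr <- if (length(p$n_primary) > 1)
    sample_int_range(p$n_primary[1], p$n_primary[2]) else p$n_primary
  base <- stats::runif(1, 0, 2 * pi)
  # queue of nodes that may split further: (node, incoming angle, depth)
  queue <- list()
  for (k in seq_len(npr)) {
    th <- base + 2 * pi * (k - 1) / npr + stats::rnorm(1, 0, deg2rad(10))
    seg <- place_segment(nodes[[1L]], th, occ)
    if (is.null(seg)) next
    to <- add_edge(1L, seg)
    queue[[length(queue) + 1]] <- list(node = to, theta = end_angle(seg$poly),
                                       depth = 1L)
  }
  while (length(queue) > 0) {
    job <- queue[[1]]; queue <- queue[-1]
    if (job$depth >= p$max_depth) next
    if (stats::runif(1) >= p$branch_prob) next
    dth <- deg2rad(stats::runif(2, p$branch_angle_deg[1],
                                p$branch_angle_deg[2]))
    at <- nodes[[job$node]]
    # commit a split only when both children fit, so every committed
    # internal node really has degree >= 3
    s1 <- place_segment(at, job$theta - dth[1], occ)
    if (is.null(s1)) next
    occ_try <- occ
    occ <- rbind(occ, s1$dense)
    s2 <- place_segment(at, job$theta + dth[2], occ)
    occ <- occ_try
    if (is.null(s2)) next
    t1 <- add_edge(job$node, s1)
    t2 <- add_edge(job$node, s2)
    queue[[length(queue) + 1]] <- list(node = t1,
                                       theta = end_angle(s1$poly),
                                       depth = job$depth + 1L)
    queue[[length(queue) + 1]] <- list(node = t2,
                                       theta = end_angle(s2$poly),
                                       depth = job$depth + 1L)
  }
  node_mat <- do.call(rbind, nodes)
  deg <- integer(nrow(node_mat))
  for (e in edges) {
    deg[e$from] <- deg[e$from] + 1L
    deg[e$to] <- deg[e$to] + 1L
  }
  list(nodes = node_mat, edges = edges, degree = deg, occ = occ)
}

#' Generate a ground-truthed synthetic scene
#'
#' Places nuclei and marker-positive cells (with process skeletons grown as
#' random binary trees) and records every truth value downstream stages
#' estimate. Rendering to pixel data is a separate step,
#' [render_channels()], which never alters the truth records.
#'
#' @param params a list from [scene_params()].
#' @param seed integer seed; identical seeds give identical scenes.
#' @return an object of class `gt_scene` with elements `params`, `seed`,
#'   `nuclei`, `cells`, `illumination`, and a `truth` list (percent positive,
#'   per-cell branch lengths in um, junction counts, and their means).
#' @export
generate_scene <- function(params = scene_params(), seed = 1) {
  p <- params
  if (any(p$image_shape < 64))
    stop("image_shape must be >= 64 x 64", call. = FALSE)
  set.seed(as.integer(seed))
  shape <- as.integer(p$image_shape)
  margin <- 14
  n_coloc <- round(p$coloc_fraction * p$n_cells)

  cells <- list()
  if (p$n_cells > 0) {
    placed <- NULL
    occ <- NULL   # occupancy points shared across cells (no crossings)
    for (ci in seq_len(p$n_cells)) {
      # rejection-sample soma positions at the configured plating sparsity
      # (morphometry protocols image sparse cultures so single cells resolve)
      for (try in 1:80) {
        ctr <- c(stats::runif(1, margin, shape[1] - margin),
                 stats::runif(1, margin, shape[2] - margin))
        if (is.null(placed) ||
            min(sqrt(rowSums(sweep(placed, 2, ctr)^2))) >=
              p$min_cell_spacing_px) break
      }
      placed <- rbind(placed, ctr)
      tree <- grow_tree(ctr, p, occ)
      occ <- tree$occ
      tree$occ <- NULL
      jn <- sum(tree$degree >= 3)
      blen_px <- vapply(tree$edges, function(e) e$length_px, numeric(1))
      cells[[ci]] <- list(
        soma_center = ctr,
        soma_radius = stats::runif(1, p$soma_radius_px[1],
                                   p$soma_radius_px[2]),
        marker = p$marker,
        skeleton = tree,
        process_width_px = p$process_width_px,
        colocalized_nucleus = NA_integer_,
        true_n_branches = length(tree$edges),
        true_junctions = jn,
        true_branch_lengths_um = blen_px * p$pixel_size_um)
    }
  }

  nuclei <- list()
  add_nucleus <- function(center) {
    list(center = center,
         semi_axes = sort(stats::runif(2, p$nucleus_axes_px[1],
                                       p$nucleus_axes_px[2]),
                          decreasing = TRUE),
         angle = stats::runif(1, 0, pi),
         intensity = stats::runif(1, p$nucleus_intensity[1],
                                  p$nucleus_intensity[2]))
  }
  if (n_coloc > 0 && p$n_cells > 0) {
    for (ci in seq_len(min(n_coloc, p$n_cells))) {
      ctr <- cells[[ci]]$soma_center + stats::rnorm(2, 0, 0.8)
      nuclei[[length(nuclei) + 1]] <- add_nucleus(ctr)
      cells[[ci]]$colocalized_nucleus <- length(nuclei)
    }
  }
  if (p$n_free_nuclei > 0) {
    have <- do.call(rbind, lapply(nuclei, `[[`, "center"))
    for (k in seq_len(p$n_free_nuclei)) {
      for (try in 1:60) {
        ctr <- c(stats::runif(1, margin, shape[1] - margin),
                 stats::runif(1, margin, shape[2] - margin))
        ok <- is.null(have) ||
          min(sqrt(rowSums(sweep(have, 2, ctr)^2))) > 16
        if (ok) break
      }
      nuclei[[length(nuclei) + 1]] <- add_nucleus(ctr)
      have <- rbind(have, ctr)
    }
  }

  # low-order polynomial vignetting, mean-normalised to 1, strictly positive
  u <- matrix(rep(seq(-1, 1, length.out = shape[2]), each = shape[1]),
              shape[1], shape[2])
  v <- matrix(rep(seq(-1, 1, length.out = shape[1]), times = shape[2]),
              shape[1], shape[2])
  cf <- stats::runif(5, -1, 1)
  g <- 1 + p$illumination_amplitude *
    (cf[1] * u + cf[2] * v + cf[3] * u^2 + cf[4] * v^2 + cf[5] * u * v -
       (u^2 + v^2) / 2)
  g <- pmax(g, 0.15)      # clip first so normalisation is exact
  g <- g / mean(g)

  all_blen <- unlist(lapply(cells, `[[`, "true_branch_lengths_um"))
  truth <- list(
    n_cells = p$n_cells,
    n_nuclei = length(nuclei),
    n_colocalized = sum(vapply(cells, function(cc)
      !is.na(cc$colocalized_nucleus), logical(1))),
    percent_positive = if (length(nuclei) > 0 && p$n_cells > 0)
      100 * min(n_coloc, p$n_cells) / length(nuclei) else NA_real_,
    branch_lengths_um = if (is.null(all_blen)) numeric() else all_blen,
    mean_branch_length_um = if (length(all_blen)) mean(all_blen) else
      NA_real_,
    total_junctions = sum(vapply(cells, `[[`, numeric(1), "true_junctions")),
    mean_junctions_per_cell = if (p$n_cells > 0)
      mean(vapply(cells, `[[`, numeric(1), "true_junctions")) else NA_real_,
    n_branches = sum(vapply(cells, `[[`, numeric(1), "true_n_branches")))

  structure(list(params = p, seed = as.integer(seed), nuclei = nuclei,
                 cells = cells, illumination = g, truth = truth),
            class = "gt_scene")
}

#' @export
print.gt_scene <- function(x, ...) {
  cat(sprintf(
    "<gt_scene> %dx%d px, %d %s cells, %d nuclei (seed %d)\n",
    x$params$image_shape[1], x$params$image_shape[2], length(x$cells),
    x$params$marker, length(x$nuclei), x$seed))
  cat(sprintf("  truth: %%positive %.1f, mean branch %.2f um, %.2f junctions/cell\n",
              x$truth$percent_positive, x$truth$mean_branch_length_um,
              x$truth$mean_junctions_per_cell))
  invisible(x)
}

# --- rasterisation helpers (exact point-to-segment distances) --------------

raster_segment_gauss <- function(acc, p1, p2, s, amp) {
  shape <- dim(acc)
  reach <- ceiling(3 * s)
  i0 <- max(1, floor(min(p1[1], p2[1])) - reach)
  i1 <- min(shape[1], ceiling(max(p1[1], p2[1])) + reach)
  j0 <- max(1, floor(min(p1[2], p2[2])) - reach)
  j1 <- min(shape[2], ceiling(max(p1[2], p2[2])) + reach)
  if (i0 > i1 || j0 > j1) return(acc)
  ii <- i0:i1; jj <- j0:j1
  Y <- matrix(rep(ii, times = length(jj)), length(ii), length(jj))
  X <- matrix(rep(jj, each = length(ii)), length(ii), length(jj))
  d <- p2 - p1
  L2 <- sum(d^2)
  if (L2 < 1e-12) {
    dist2 <- (Y - p1[1])^2 + (X - p1[2])^2
  } else {
    t <- pmin(pmax(((Y - p1[1]) * d[1] + (X - p1[2]) * d[2]) / L2, 0), 1)
    dist2 <- (Y - (p1[1] + t * d[1]))^2 + (X - (p1[2] + t * d[2]))^2
  }
  val <- amp * exp(-dist2 / (2 * s^2))
  acc[ii, jj] <- pmax(acc[ii, jj], val)
  acc
}

raster_polyline_gauss <- function(acc, poly, s, amp) {
  for (k in seq_len(nrow(poly) - 1))
    acc <- raster_segment_gauss(acc, poly[k, ], poly[k + 1, ], s, amp)
  acc
}

raster_disc <- function(acc, center, radius, amp, soft = 0.8) {
  shape <- dim(acc)
  reach <- ceiling(radius + 4 * soft + 2)
  i0 <- max(1, floor(center[1]) - reach)
  i1 <- min(shape[1], ceiling(center[1]) + reach)
  j0 <- max(1, floor(center[2]) - reach)
  j1 <- min(shape[2], ceiling(center[2]) + reach)
  if (i0 > i1 || j0 > j1) return(acc)
  ii <- i0:i1; jj <- j0:j1
  Y <- matrix(rep(ii, times = length(jj)), length(ii), length(jj))
  X <- matrix(rep(jj, each = length(ii)), length(ii), length(jj))
  dd <- sqrt((Y - center[1])^2 + (X - center[2])^2)
  val <- amp / (1 + exp((dd - radius) / soft))
  acc[ii, jj] <- pmax(acc[ii, jj], val)
  acc
}

raster_ellipse <- function(acc, center, axes, angle, amp, soft = 0.12) {
  shape <- dim(acc)
  reach <- ceiling(max(axes) + 4)
  i0 <- max(1, floor(center[1]) - reach)
  i1 <- min(shape[1], ceiling(center[1]) + reach)
  j0 <- max(1, floor(center[2]) - reach)
  j1 <- min(shape[2], ceiling(center[2]) + reach)
  if (i0 > i1 || j0 > j1) return(acc)
  ii <- i0:i1; jj <- j0:j1
  Y <- matrix(rep(ii, times = length(jj)), length(ii), length(jj)) - center[1]
  X <- matrix(rep(jj, each = length(ii)), length(ii), length(jj)) - center[2]
  xr <- cos(angle) * X + sin(angle) * Y
  yr <- -sin(angle) * X + cos(angle) * Y
  uu <- sqrt((xr / axes[1])^2 + (yr / axes[2])^2)
  val <- amp / (1 + exp((uu - 1) / soft))
  acc[ii, jj] <- pmax(acc[ii, jj], val)
  acc
}

# noiseless per-channel signals (before illumination, bleed and noise)
scene_signals <- function(scene) {
  shape <- scene$params$image_shape
  dapi <- matrix(0, shape[1], shape[2])
  for (nu in scene$nuclei)
    dapi <- raster_ellipse(dapi, nu$center, nu$semi_axes, nu$angle,
                           nu$intensity)
  marker <- matrix(0, shape[1], shape[2])
  s <- scene$params$process_width_px / 2
  for (cc in scene$cells) {
    marker <- raster_disc(marker, cc$soma_center, cc$soma_radius,
                          scene$params$soma_intensity)
    for (e in cc$skeleton$edges)
      marker <- raster_polyline_gauss(marker, e$poly, s,
                                      scene$params$process_contrast)
  }
  list(dapi = dapi, marker = marker)
}

#' Gaussian blur of a matrix
#'
#' Separable Gaussian convolution with mirrored borders; for large sigma
#' (> 8 px) an iterated box filter of matched variance is used, which is
#' O(1) per pixel and indistinguishable for the smooth-background uses the
#' pipeline has for wide blurs.
#'
#' @param m numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix.
#' @export
gauss_blur <- function(m, sigma) {
  if (sigma <= 0) return(m)
  if (sigma > 8) return(cpp_box_gauss(m, sigma))
  k <- gauss_kernel(sigma, 0)
  cpp_conv_sep(m, k, k)
}

# Gaussian (derivative) kernels for correlation-style separable filtering
# (cpp_conv_sep computes sum_k k[d] * m[i + d], i.e. correlation, so the
# first-derivative kernel carries +x, not -x).
gauss_kernel <- function(sigma, order = 0) {
  r <- max(1L, ceiling(3.5 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  if (order == 0) return(g)
  if (order == 1) return(x / sigma^2 * g)
  if (order == 2) return((x^2 - sigma^2) / sigma^4 * g)
  stop("order must be 0, 1 or 2")
}

add_noise <- function(sig, photon_scale, read_sd, seed) {
  set.seed(as.integer(seed %% .Machine$integer.max))
  out <- sig
  if (is.finite(photon_scale) && photon_scale > 0) {
    lam <- pmax(sig, 0) * photon_scale
    out <- matrix(stats::rpois(length(lam), lam) / photon_scale,
                  nrow(sig), ncol(sig))
  }
  if (read_sd > 0)
    out <- out + matrix(stats::rnorm(length(sig), 0, read_sd),
                        nrow(sig), ncol(sig))
  out
}

#' Render a scene into DAPI and marker channel images
#'
#' The marker channel receives additive, Gaussian-blurred DAPI leakage scaled
#' by `bleed_coefficient` (the artifact the solidity/overlap ROI filters must
#' remove); both channels are multiplied by the scene's vignetting field,
#' degraded with Poisson shot noise and Gaussian read noise (per-channel
#' sub-seeds `seed + 101` for DAPI and `seed + 202` for the marker), and
#' quantised to the stored bit depth. Truth records are not touched.
#'
#' @param scene a `gt_scene` from [generate_scene()].
#' @return list with `dapi` and `marker` [channel_image()] objects.
#' @export
render_channels <- function(scene) {
  stopifnot(inherits(scene, "gt_scene"))
  p <- scene$params
  sig <- scene_signals(scene)
  bleed <- if (p$bleed_coefficient > 0)
    p$bleed_coefficient * gauss_blur(sig$dapi, p$bleed_blur_sigma)
  else 0
  dapi_t <- scene$illumination * sig$dapi
  marker_t <- scene$illumination * (sig$marker + bleed)
  dapi_n <- add_noise(dapi_t, p$photon_scale, p$read_sd, scene$seed + 101)
  marker_n <- add_noise(marker_t, p$photon_scale, p$read_sd,
                        scene$seed + 202)
  maxv <- 2^p$bit_depth - 1
  q <- function(m) pmin(pmax(round(m), 0), maxv)
  list(
    dapi = channel_image(q(dapi_n), "DAPI", p$pixel_size_um, p$bit_depth,
                         provenance = "render"),
    marker = channel_image(q(marker_n), p$marker, p$pixel_size_um,
                           p$bit_depth, provenance = "render"))
}

#' Ground-truth occupancy masks of a scene
#'
#' Binary rasters of where true cells (soma + processes) and true nuclei lie,
#' computed from the noiseless signals. Used to classify detected ROIs as
#' genuine cells versus pure bleed-through artifacts in validation studies.
#'
#' @param scene a `gt_scene`.
#' @param frac signal fraction (of the peak amplitudes) defining occupancy.
#' @return list of logical matrices `cell` and `nucleus`.
#' @export
truth_masks <- function(scene, frac = 0.25) {
  sig <- scene_signals(scene)
  cell_cut <- frac * min(scene$params$soma_intensity,
                         scene$params$process_contrast)
  nuc_cut <- frac * scene$params$nucleus_intensity[1]
  list(cell = sig$marker > cell_cut, nucleus = sig$dapi > nuc_cut)
}

#' Write a rendered scene as multi-page TIFF plus JSON truth sidecar
#'
#' Page 1 is DAPI, page 2 the marker channel. The sidecar (`<path>.json`)
#' stores the scene's truth summary and parameters.
#'
#' @param scene a `gt_scene`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_scene <- function(scene, path) {
  ch <- render_channels(scene)
  write_tiff(list(ch$dapi$pixels, ch$marker$pixels), path,
             bits = scene$params$bit_depth)
  sidecar <- list(seed = scene$seed, marker = scene$params$marker,
                  pixel_size_um = scene$params$pixel_size_um,
                  truth = scene$truth)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

# ---------------------------------------------------------------------------
# hierarchical cohort measurement tables

#' Describe a nested two-group cohort
#'
#' Donor lines nested in diagnostic groups (Ctrl vs SCZ), fields of view
#' nested in lines. Defaults mirror the reference study's design: 7 lines
#' per group with 8-13 fields of view each, branch-length and junction-number
#' readouts with grand means 0.624 and 0.409 and SCZ shifts +0.052 and
#' +0.102 (the reported group contrasts), between-line SD 0.10 and
#' within-line SD 0.15.
#'
#' @param n_lines_per_group donor lines per group.
#' @param n_fov_per_line integer range (length 2) or single count of fields
#'   of view per line.
#' @param metrics metric names.
#' @param grand_mean,group_effect,line_sd,fov_sd scalars or per-metric
#'   vectors (recycled across `metrics`).
#' @param seed integer seed.
#' @return an object of class `cohort_design`.
#' @export
cohort_design <- function(n_lines_per_group = 7,
                          n_fov_per_line = c(8, 13),
                          metrics = c("avg_branch_length",
                                      "avg_junction_number"),
                          grand_mean = c(0.624, 0.409),
                          group_effect = c(0.052, 0.102),
                          line_sd = 0.10,
                          fov_sd = 0.15,
                          seed = 1) {
  if (n_lines_per_group < 1 || any(n_fov_per_line < 1))
    stop("all counts must be >= 1", call. = FALSE)
  if (any(line_sd < 0) || any(fov_sd < 0))
    stop("SDs must be >= 0", call. = FALSE)
  m <- length(metrics)
  structure(list(
    n_lines_per_group = as.integer(n_lines_per_group),
    n_fov_per_line = as.integer(n_fov_per_line),
    metrics = metrics,
    grand_mean = rep_len(grand_mean, m),
    group_effect = rep_len(group_effect, m),
    line_sd = rep_len(line_sd, m),
    fov_sd = rep_len(fov_sd, m),
    seed = as.integer(seed)), class = "cohort_design")
}

#' Simulate a hierarchical measurement table
#'
#' Each value is grand mean + group effect (SCZ only) + a per-line random
#' intercept (SD `line_sd`) + field-of-view noise (SD `fov_sd`). Line
#' intercepts are drawn independently per metric.
#'
#' @param design a [cohort_design()].
#' @return a `data.frame` with columns `group`, `line`, `fov`, `metric`,
#'   `value` (a MeasurementTable).
#' @export
simulate_measurements <- function(design) {
  stopifnot(inherits(design, "cohort_design"))
  set.seed(design$seed)
  groups <- c("Ctrl", "SCZ")
  out <- list()
  for (g in groups) {
    for (li in seq_len(design$n_lines_per_group)) {
      line_id <- sprintf("%s_L%02d", g, li)
      nf <- if (length(design$n_fov_per_line) > 1)
        sample_int_range(design$n_fov_per_line[1], design$n_fov_per_line[2])
      else design$n_fov_per_line
      for (mi in seq_along(design$metrics)) {
        b <- stats::rnorm(1, 0, design$line_sd[mi])
        mu <- design$grand_mean[mi] +
          if (g == "SCZ") design$group_effect[mi] else 0
        vals <- mu + b + stats::rnorm(nf, 0, design$fov_sd[mi])
        out[[length(out) + 1]] <- data.frame(
          group = g, line = line_id, fov = seq_len(nf),
          metric = design$metrics[mi], value = vals,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out)
}

#' Write / read a measurement table as CSV
#'
#' @param table a measurement table (`group`, `line`, `fov`, `metric`,
#'   `value`).
#' @param path CSV path.
#' @return `path` invisibly / the table.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
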