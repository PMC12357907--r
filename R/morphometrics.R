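# Field-of-view morphometrics: percent marker-positive cells, average cell
# size, and the two process readouts (average branch length, average junction
# number) computed by two independent backends — Steger-style ridge detection
# on the greyscale image and branch/junction analysis of the thinned binary
# mask.

#' Percent marker-positive cells
#'
#' A marker ROI counts as a marker-positive cell when its pixel set contains
#' the centroid of at least one DAPI ROI (the colocalization rule). The
#' result is `100 * n_positive / n_DAPI`, capped at 100.
#'
#' @param marker_rois,dapi_rois `roi_set`s from images of identical shape.
#' @return percentage in `[0, 100]`, or `NA` when there are no DAPI ROIs.
#' @export
percent_positive <- function(marker_rois, dapi_rois) {
  if (length(dapi_rois) == 0) {
    message("percent_positive: no DAPI ROIs; returning NA")
    return(NA_real_)
  }
  if (length(marker_rois) == 0) return(0)
  shp <- attr(marker_rois, "shape")
  lab <- matrix(0L, shp[1], shp[2])
  for (r in marker_rois) lab[r$pixels] <- r$label
  hit <- integer(0)
  for (d in dapi_rois) {
    ci <- pmin(pmax(round(d$centroid[1]), 1), shp[1])
    cj <- pmin(pmax(round(d$centroid[2]), 1), shp[2])
    if (lab[ci, cj] > 0) hit <- c(hit, lab[ci, cj])
  }
  min(100, 100 * length(unique(hit)) / length(dapi_rois))
}

#' Average cell size
#'
#' Total positive area divided by the cell count.
#'
#' @param mask a [binary_mask()] (or logical matrix) of positive signal.
#' @param cell_count number of cells (>= 1; 0 yields `NA`).
#' @param pixel_size_um pixel size; areas are reported in um^2 when given
#'   (px^2 for the default of 1).
#' @return average area per cell.
#' @export
average_cell_size <- function(mask, cell_count, pixel_size_um = 1) {
  if (is.na(cell_count) || cell_count < 1) {
    message("average_cell_size: cell_count < 1; returning NA")
    return(NA_real_)
  }
  px <- as_pixel_matrix(mask)
  sum(px != 0) * pixel_size_um^2 / cell_count
}

# contrast (grey levels) -> threshold on the second-directional-derivative
# magnitude, assuming a Gaussian line profile of sd s = sigma * sqrt(3)/2
# (the width the detector is tuned for under the sigma >= w/sqrt(3) rule):
# a profile c*exp(-x^2/(2 s^2)) smoothed at scale sigma has second-derivative
# magnitude c*s / (s^2 + sigma^2)^(3/2) on the centreline.
ridge_salience_threshold <- function(contrast, sigma) {
  s <- sigma * sqrt(3) / 2
  contrast * s / (s^2 + sigma^2)^1.5
}

#' Detect curvilinear structures (Steger ridge detection)
#'
#' Line points are pixels where the largest-magnitude eigenvalue of the
#' Gaussian-derivative Hessian is negative (bright line) and the sub-pixel
#' maximum along the corresponding eigenvector falls inside the pixel.
#' Points are linked into polylines with hysteresis: a polyline starts at a
#' point whose salience exceeds the `high_contrast`-equivalent threshold and
#' extends through points above the `low_contrast` one. Polylines are split
#' at junctions, so each polyline is one branch.
#'
#' @param image a [channel_image()].
#' @param sigma derivative scale in px; detects lines of width about
#'   `sigma * sqrt(3)`.
#' @param low_contrast,high_contrast hysteresis thresholds expressed as line
#'   contrast in grey levels (`0 <= low < high`).
#' @param min_points minimum polyline length in points.
#' @param max_eigen_ratio line-versus-blob test: a point is accepted only if
#'   the Hessian's second eigenvalue is at most this fraction of the first in
#'   magnitude (ideal lines have ratio near 0, blobs and line end-caps near
#'   1).
#' @param junction_radius pairing distance (px) within which two polylines'
#'   closest approach counts as a junction.
#' @return a `line_set`: `polylines` (list of n x 2 sub-pixel (row, col)
#'   matrices), `lengths_um`, `junction_points`, `total_length_um`.
#' @export
detect_ridges <- function(image, sigma = 1.8, low_contrast = 20,
                          high_contrast = 55, min_points = 6,
                          max_eigen_ratio = 0.6, junction_radius = 3) {
  if (low_contrast < 0 || low_contrast >= high_contrast)
    stop("need 0 <= low_contrast < high_contrast", call. = FALSE)
  px <- as_pixel_matrix(image)
  psz <- if (inherits(image, "channel_image")) image$pixel_size_um else 1
  nr <- nrow(px); nc <- ncol(px)
  g0 <- gauss_kernel(sigma, 0)
  g1 <- gauss_kernel(sigma, 1)
  g2 <- gauss_kernel(sigma, 2)
  ry <- cpp_conv_sep(px, g1, g0)   # d/d(row)
  rx <- cpp_conv_sep(px, g0, g1)   # d/d(col)
  ryy <- cpp_conv_sep(px, g2, g0)
  rxx <- cpp_conv_sep(px, g0, g2)
  rxy <- cpp_conv_sep(px, g1, g1)

  tr <- ryy + rxx
  dd <- sqrt(pmax((ryy - rxx)^2 + 4 * rxy^2, 0))
  l1 <- (tr - dd) / 2   # most negative eigenvalue (bright lines)
  l2 <- (tr + dd) / 2
  strength <- -l1
  linelike <- l2 >= 0 | abs(l2) <= max_eigen_ratio * abs(l1)
  # eigenvector of l1 = line normal; pick the better-conditioned expression
  e1y <- rxy; e1x <- l1 - ryy
  alt <- abs(l1 - rxx) > abs(l1 - ryy)
  e1y[alt] <- (l1 - rxx)[alt]; e1x[alt] <- rxy[alt]
  nrm <- sqrt(e1y^2 + e1x^2)
  ok_n <- nrm > 1e-12
  ny <- ifelse(ok_n, e1y / nrm, 0)
  nx <- ifelse(ok_n, e1x / nrm, 1)
  tt <- -(ry * ny + rx * nx) / ifelse(abs(l1) > 1e-12, l1, 1)
  low_thr <- ridge_salience_threshold(low_contrast, sigma)
  high_thr <- ridge_salience_threshold(high_contrast, sigma)
  valid <- ok_n & linelike & strength >= low_thr &
    abs(tt * ny) <= 0.5 & abs(tt * nx) <= 0.5
  # weaker evidence used only to bridge single-pixel gaps during linking
  # (noise flickers one centreline pixel below threshold or out of the
  # sub-pixel containment band and would otherwise break the line)
  weak <- ok_n & linelike & strength >= 0.4 * low_thr &
    abs(tt * ny) <= 0.5 & abs(tt * nx) <= 0.5
  spy <- row(px) + tt * ny
  spx <- col(px) + tt * nx

  polylines <- link_ridge_points(valid, weak, strength, ny, nx, spy, spx,
                                 high_thr)
  polylines <- Filter(function(p) nrow(p) >= min_points, polylines)
  jp <- ridge_junctions(polylines, junction_radius)
  polylines <- split_polylines_at(polylines, jp)
  polylines <- Filter(function(p) nrow(p) >= min_points, polylines)
  lens <- vapply(polylines, polyline_length, numeric(1)) * psz
  structure(list(polylines = polylines, lengths_um = lens,
                 junction_points = jp,
                 total_length_um = sum(lens), pixel_size_um = psz),
            class = "line_set")
}

#' @export
print.line_set <- function(x, ...) {
  cat(sprintf("<line_set> %d polylines, %d junctions, total length %.1f um\n",
              length(x$polylines), nrow(x$junction_points),
              x$total_length_um))
  invisible(x)
}

# greedy hysteresis linking of ridge points into polylines; `weak` points
# may be traversed, but never two in a row
link_ridge_points <- function(valid, weak, strength, ny, nx, spy, spx,
                              high_thr) {
  nr <- nrow(valid); nc <- ncol(valid)
  idx <- which(valid)
  if (length(idx) == 0) return(list())
  ord <- idx[order(strength[idx], decreasing = TRUE)]
  seeds <- ord[strength[ord] >= high_thr]
  used <- matrix(FALSE, nr, nc)
  offs <- cbind(di = c(-1, -1, -1, 0, 0, 1, 1, 1),
                dj = c(-1, 0, 1, -1, 1, -1, 0, 1))
  off_ang <- atan2(offs[, 1], offs[, 2])
  polylines <- list()
  for (s in seeds) {
    if (used[s]) next
    i0 <- ((s - 1) %% nr) + 1
    j0 <- ((s - 1) %/% nr) + 1
    used[s] <- TRUE
    halves <- vector("list", 2)
    half_k <- 0
    for (dirn in c(1, -1)) {
      half_k <- half_k + 1
      pts <- list()
      wk <- logical(0)
      i <- i0; j <- j0
      prev_weak <- FALSE
      # tangent is perpendicular to the normal
      td <- dirn * c(-nx[i, j], ny[i, j])
      repeat {
        ta <- atan2(td[1], td[2])
        dang <- abs(((off_ang - ta + pi) %% (2 * pi)) - pi)
        cands <- which(dang <= pi / 4 + 1e-9)
        pick <- function(mask) {
          best <- NULL; best_score <- Inf
          for (k in cands) {
            ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
            if (ii < 1 || ii > nr || jj < 1 || jj > nc) next
            if (!mask[ii, jj] || used[ii, jj]) next
            dist <- sqrt((spy[ii, jj] - spy[i, j])^2 +
                           (spx[ii, jj] - spx[i, j])^2)
            # normal angle difference modulo pi
            a1 <- atan2(ny[i, j], nx[i, j])
            a2 <- atan2(ny[ii, jj], nx[ii, jj])
            db <- abs(((a1 - a2 + pi / 2) %% pi) - pi / 2)
            score <- dist + db
            if (score < best_score) { best_score <- score; best <- c(ii, jj) }
          }
          best
        }
        best <- pick(valid)
        is_weak <- FALSE
        if (is.null(best) && !prev_weak) {
          best <- pick(weak)
          is_weak <- !is.null(best)
        }
        if (is.null(best)) break
        prev_weak <- is_weak
        td <- c(best[1] - i, best[2] - j)
        td <- td / sqrt(sum(td^2))
        i <- best[1]; j <- best[2]
        used[i, j] <- TRUE
        pts[[length(pts) + 1]] <- c(spy[i, j], spx[i, j])
        wk[length(pts)] <- is_weak
      }
      # weak points are gap bridges; a terminal weak point is a drifted
      # tail, not a bridge — trim it
      while (length(pts) && wk[length(pts)]) {
        pts[[length(pts)]] <- NULL
        wk <- wk[-length(wk)]
      }
      if (length(pts)) halves[[half_k]] <- do.call(rbind, pts)
    }
    fwd <- halves[[1]]; bwd <- halves[[2]]
    poly <- rbind(if (!is.null(bwd)) bwd[rev(seq_len(nrow(bwd))), ,
                                         drop = FALSE],
                  matrix(c(spy[i0, j0], spx[i0, j0]), 1, 2),
                  fwd)
    if (nrow(poly) >= 2) polylines[[length(polylines) + 1]] <- poly
  }
  polylines
}

# Junctions of a line set. Two kinds of evidence:
#  - closest approach (< radius px) between two polylines where at least one
#    of the matched points is interior — a T-meeting or a crossing; pure
#    end-to-end approaches are continuations (e.g. a kink split during
#    linking), not junctions;
#  - >= 3 polyline endpoints within 2*radius — several processes converging
#    on a soma-scale spot.
# Nearby candidates are merged single-link at 2*radius.
ridge_junctions <- function(polylines, radius = 3) {
  np <- length(polylines)
  cand <- list()
  if (np >= 2) {
    bb <- t(vapply(polylines, function(p)
      c(min(p[, 1]), min(p[, 2]), max(p[, 1]), max(p[, 2])), numeric(4)))
    for (a in 1:(np - 1)) for (b in (a + 1):np) {
      if (bb[a, 1] > bb[b, 3] + radius || bb[b, 1] > bb[a, 3] + radius ||
          bb[a, 2] > bb[b, 4] + radius || bb[b, 2] > bb[a, 4] + radius) next
      pa <- polylines[[a]]; pb <- polylines[[b]]
      d2 <- outer(pa[, 1], pb[, 1], "-")^2 + outer(pa[, 2], pb[, 2], "-")^2
      w <- which.min(d2)
      if (d2[w] < radius^2) {
        ia <- ((w - 1) %% nrow(pa)) + 1
        ib <- ((w - 1) %/% nrow(pa)) + 1
        int_a <- ia > 3 && ia < nrow(pa) - 2
        int_b <- ib > 3 && ib < nrow(pb) - 2
        if (int_a || int_b)
          cand[[length(cand) + 1]] <- (pa[ia, ] + pb[ib, ]) / 2
      }
    }
  }
  # meeting endpoints
  if (np >= 3) {
    ends <- do.call(rbind, lapply(polylines, function(p)
      rbind(p[1, ], p[nrow(p), ])))
    if (nrow(ends) >= 3) {
      er <- 2 * radius
      d2 <- outer(ends[, 1], ends[, 1], "-")^2 +
        outer(ends[, 2], ends[, 2], "-")^2
      near <- rowSums(d2 < er^2)
      for (k in which(near >= 3))
        cand[[length(cand) + 1]] <- colMeans(ends[d2[k, ] < er^2, ,
                                                  drop = FALSE])
    }
  }
  if (length(cand) == 0) return(matrix(numeric(0), 0, 2))
  pts <- do.call(rbind, cand)
  # merge nearby candidates (single-link, slightly wider than the pairing
  # radius so that the several pairwise approaches around one soma or one
  # crossing collapse into a single junction)
  mradius <- 2 * radius
  merged <- list()
  taken <- rep(FALSE, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    if (taken[k]) next
    grp <- k
    repeat {
      d2 <- (pts[, 1] - mean(pts[grp, 1]))^2 +
        (pts[, 2] - mean(pts[grp, 2]))^2
      add <- which(!taken & d2 < mradius^2)
      if (all(add %in% grp)) break
      grp <- union(grp, add)
    }
    taken[grp] <- TRUE
    merged[[length(merged) + 1]] <- colMeans(pts[grp, , drop = FALSE])
  }
  do.call(rbind, merged)
}

split_polylines_at <- function(polylines, junctions) {
  if (nrow(junctions) == 0) return(polylines)
  out <- list()
  for (p in polylines) {
    d2min <- rep(Inf, nrow(p))
    for (k in seq_len(nrow(junctions)))
      d2min <- pmin(d2min, (p[, 1] - junctions[k, 1])^2 +
                      (p[, 2] - junctions[k, 2])^2)
    cutpts <- which(d2min < 1.5^2)
    # interior cuts only
    cutpts <- cutpts[cutpts > 1 & cutpts < nrow(p)]
    if (length(cutpts) == 0) { out[[length(out) + 1]] <- p; next }
    # collapse runs of adjacent cut indices to their centre
    runs <- split(cutpts, cumsum(c(1, diff(cutpts) > 2)))
    cuts <- vapply(runs, function(r) r[ceiling(length(r) / 2)], numeric(1))
    b <- c(1, cuts, nrow(p))
    for (k in seq_len(length(b) - 1)) {
      seg <- p[b[k]:b[k + 1], , drop = FALSE]
      if (nrow(seg) >= 2) out[[length(out) + 1]] <- seg
    }
  }
  out
}

# ---------------------------------------------------------------------------
# skeleton backend

#' Skeletonize a mask and build its branch/junction graph
#'
#' Topology-preserving thinning to a 1-px skeleton, followed by graph
#' construction: nodes are endpoints (1 skeleton neighbour) and junction
#' clusters (>= 3 neighbours, 8-adjacent junction pixels merged); edges are
#' the pixel paths between them with length summed as 1 per orthogonal and
#' sqrt(2) per diagonal step (times pixel size). Terminal spurs shorter than
#' `prune_px` are removed and pass-through nodes left behind are merged, so
#' pruning never fragments a true branch.
#'
#' @param mask a [binary_mask()].
#' @param pixel_size_um pixel size for um lengths.
#' @param prune_px spur-pruning length in pixels (0 disables).
#' @param merge_junctions_px junction nodes closer than this (along a
#'   connecting edge) are contracted into one: thinning wide junction areas
#'   often splinters one anatomical branch point into two nearby 3-way
#'   nodes joined by a pixel-scale edge (0 disables).
#' @return a `skeleton_graph`: `nodes` (data.frame id, y, x, degree),
#'   `edges` (list of `path`, `length_px`, `length_um`, `n1`, `n2`),
#'   `n_junctions`, `skeleton` (logical matrix).
#' @export
skeletonize_mask <- function(mask, pixel_size_um = 1, prune_px = 4,
                             merge_junctions_px = 4) {
  m <- as_pixel_matrix(mask)
  storage.mode(m) <- "logical"
  sk <- cpp_thin(m)
  g <- skeleton_graph_from(sk)
  if (prune_px > 0) g <- prune_graph(g, prune_px)
  if (merge_junctions_px > 0) {
    g <- contract_junctions(g, merge_junctions_px)
    if (prune_px > 0) g <- prune_graph(g, prune_px)
  }
  deg <- graph_degrees(g)
  g$nodes$degree <- deg
  g$n_junctions <- sum(deg >= 3)
  g$pixel_size_um <- pixel_size_um
  edt <- sqrt(cpp_edt_sq(m))
  for (k in seq_along(g$edges)) {
    e <- g$edges[[k]]
    # Two geometric corrections to the traced path length: a branch reaches
    # the junction point itself (extend to the cluster-averaged node
    # centroids), and thinning stops about one band half-width short of the
    # mask tip (extend terminal ends by the local distance-to-background).
    ext <- 0
    for (side in 1:2) {
      nid <- if (side == 1) e$n1 else e$n2
      endpt <- if (side == 1) e$path[1, ] else e$path[nrow(e$path), ]
      if (nid > 0 && deg[nid] >= 3) {
        ext <- ext + sqrt(sum((endpt - c(g$nodes$y[nid],
                                         g$nodes$x[nid]))^2))
      } else if (nid > 0 && deg[nid] == 1) {
        # edt = 1 on a 1-px-wide line, where no correction is due
        ext <- ext + max(0, edt[endpt[1], endpt[2]] - 1)
      }
    }
    g$edges[[k]]$length_px <- e$length_px + ext
    g$edges[[k]]$length_um <- (e$length_px + ext) * pixel_size_um
  }
  g$skeleton <- sk
  class(g) <- "skeleton_graph"
  g
}

#' @export
print.skeleton_graph <- function(x, ...) {
  cat(sprintf("<skeleton_graph> %d nodes, %d branches, %d junctions\n",
              nrow(x$nodes), length(x$edges), x$n_junctions))
  invisible(x)
}

path_steps_length <- function(path) {
  if (nrow(path) < 2) return(0)
  d <- abs(path[-1, , drop = FALSE] - path[-nrow(path), , drop = FALSE])
  sum(ifelse(d[, 1] + d[, 2] == 2, sqrt(2), 1))
}

# build node/edge graph from a thinned skeleton
skeleton_graph_from <- function(sk) {
  nr <- nrow(sk); nc <- ncol(sk)
  empty <- list(nodes = data.frame(id = integer(), y = numeric(),
                                   x = numeric(), degree = integer()),
                edges = list(), n_junctions = 0L)
  if (!any(sk)) return(empty)
  deg <- matrix(0L, nr, nc)
  for (di in -1:1) for (dj in -1:1)
    if (di != 0 || dj != 0) deg <- deg + shift_mat(sk, di, dj, FALSE)
  deg[!sk] <- 0L
  node_px <- sk & (deg != 2L)
  # merge 8-adjacent junction pixels into single nodes; endpoints alone
  jmask <- sk & deg >= 3L
  jlab <- cpp_label(jmask, 8L)
  njc <- max(jlab)
  node_id <- matrix(0L, nr, nc)
  node_id[jmask] <- jlab[jmask]
  epts <- which(sk & deg <= 1L, arr.ind = TRUE)
  if (nrow(epts) > 0)
    node_id[epts] <- njc + seq_len(nrow(epts))
  n_nodes <- njc + nrow(epts)
  ny <- numeric(n_nodes); nx <- numeric(n_nodes)
  if (n_nodes > 0) {
    cc <- which(node_id > 0, arr.ind = TRUE)
    ids <- node_id[cc]
    ny <- tapply(cc[, 1], ids, mean)[as.character(seq_len(n_nodes))]
    nx <- tapply(cc[, 2], ids, mean)[as.character(seq_len(n_nodes))]
  }
  offs <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  nbrs <- function(i, j) {
    out <- NULL
    for (k in 1:8) {
      ii <- i + offs[k, 1]; jj <- j + offs[k, 2]
      if (ii >= 1 && ii <= nr && jj >= 1 && jj <= nc && sk[ii, jj])
        out <- rbind(out, c(ii, jj))
    }
    out
  }
  visited <- matrix(FALSE, nr, nc)   # consumed degree-2 pixels
  edges <- list()
  node_cells <- which(node_id > 0, arr.ind = TRUE)
  add_edge <- function(path, a, b) {
    edges[[length(edges) + 1]] <<- list(
      path = path, n1 = a, n2 = b, length_px = path_steps_length(path))
  }
  if (nrow(node_cells) > 0) {
    for (q in seq_len(nrow(node_cells))) {
      i <- node_cells[q, 1]; j <- node_cells[q, 2]
      a <- node_id[i, j]
      nb <- nbrs(i, j)
      if (is.null(nb)) next
      for (t in seq_len(nrow(nb))) {
        vi <- nb[t, 1]; vj <- nb[t, 2]
        if (node_id[vi, vj] > 0) {
          # direct node-node contact; emit once, skip intra-cluster pairs
          b <- node_id[vi, vj]
          if (b > a) add_edge(rbind(c(i, j), c(vi, vj)), a, b)
          next
        }
        if (visited[vi, vj]) next
        path <- rbind(c(i, j), c(vi, vj))
        visited[vi, vj] <- TRUE
        pi <- i; pj <- j; ci <- vi; cj <- vj
        repeat {
          nb2 <- nbrs(ci, cj)
          nxt <- NULL
          for (u in seq_len(nrow(nb2))) {
            ui <- nb2[u, 1]; uj <- nb2[u, 2]
            if (ui == pi && uj == pj) next
            # avoid stepping back into the path via diagonal shortcuts
            if (node_id[ui, uj] > 0 && node_id[ui, uj] == a &&
                nrow(path) <= 2) next
            if (node_id[ui, uj] == 0 && visited[ui, uj]) next
            nxt <- c(ui, uj); break
          }
          if (is.null(nxt)) { add_edge(path, a, 0L); break }
          path <- rbind(path, nxt)
          if (node_id[nxt[1], nxt[2]] > 0) {
            add_edge(path, a, node_id[nxt[1], nxt[2]])
            break
          }
          visited[nxt[1], nxt[2]] <- TRUE
          pi <- ci; pj <- cj; ci <- nxt[1]; cj <- nxt[2]
        }
      }
    }
  }
  # isolated cycles: all remaining unvisited degree-2 pixels
  rem <- which(sk & deg == 2L & !visited & node_id == 0L, arr.ind = TRUE)
  while (nrow(rem) > 0) {
    i <- rem[1, 1]; j <- rem[1, 2]
    path <- matrix(c(i, j), 1, 2)
    visited[i, j] <- TRUE
    pi <- -1; pj <- -1; ci <- i; cj <- j
    repeat {
      nb2 <- nbrs(ci, cj)
      nxt <- NULL
      for (u in seq_len(nrow(nb2))) {
        ui <- nb2[u, 1]; uj <- nb2[u, 2]
        if ((ui == pi && uj == pj) || visited[ui, uj]) next
        nxt <- c(ui, uj); break
      }
      if (is.null(nxt)) break
      path <- rbind(path, nxt)
      visited[nxt[1], nxt[2]] <- TRUE
      pi <- ci; pj <- cj; ci <- nxt[1]; cj <- nxt[2]
    }
    if (nrow(path) >= 2) {
      path <- rbind(path, path[1, ])  # close the loop
      edges[[length(edges) + 1]] <- list(path = path, n1 = 0L, n2 = 0L,
                                         length_px = path_steps_length(path))
    }
    rem <- which(sk & deg == 2L & !visited & node_id == 0L, arr.ind = TRUE)
  }
  nodes <- data.frame(id = seq_len(n_nodes), y = as.numeric(ny),
                      x = as.numeric(nx), degree = 0L)
  list(nodes = nodes, edges = edges, n_junctions = 0L)
}

graph_degrees <- function(g) {
  deg <- integer(nrow(g$nodes))
  for (e in g$edges) {
    if (e$n1 > 0) deg[e$n1] <- deg[e$n1] + 1L
    if (e$n2 > 0) deg[e$n2] <- deg[e$n2] + 1L
  }
  deg
}

# contract short edges joining two junction nodes into a single node
contract_junctions <- function(g, merge_px) {
  repeat {
    deg <- graph_degrees(g)
    idx <- which(vapply(g$edges, function(e)
      e$n1 > 0 && e$n2 > 0 && e$n1 != e$n2 &&
        deg[e$n1] >= 3 && deg[e$n2] >= 3 && e$length_px < merge_px,
      logical(1)))
    if (length(idx) == 0) break
    e <- g$edges[[idx[1]]]
    a <- e$n1; b <- e$n2
    g$edges <- g$edges[-idx[1]]
    for (k in seq_along(g$edges)) {
      if (g$edges[[k]]$n1 == b) g$edges[[k]]$n1 <- a
      if (g$edges[[k]]$n2 == b) g$edges[[k]]$n2 <- a
    }
    g$nodes$y[a] <- (g$nodes$y[a] + g$nodes$y[b]) / 2
    g$nodes$x[a] <- (g$nodes$x[a] + g$nodes$x[b]) / 2
    keep <- vapply(g$edges, function(e2)
      !(e2$n1 == a && e2$n2 == a && e2$length_px < merge_px), logical(1))
    g$edges <- g$edges[keep]
  }
  g
}

# remove terminal spurs shorter than prune_px, then merge pass-through nodes
prune_graph <- function(g, prune_px) {
  repeat {
    deg <- graph_degrees(g)
    drop <- integer(0)
    for (k in seq_along(g$edges)) {
      e <- g$edges[[k]]
      if (e$length_px >= prune_px) next
      # a spur hangs loose on one side (endpoint node or a dead-end trace)
      # and is anchored at a junction on the other
      loose1 <- e$n1 == 0 || deg[e$n1] == 1L
      loose2 <- e$n2 == 0 || deg[e$n2] == 1L
      anchor1 <- e$n1 > 0 && deg[e$n1] >= 3L
      anchor2 <- e$n2 > 0 && deg[e$n2] >= 3L
      if ((loose1 && anchor2) || (loose2 && anchor1)) drop <- c(drop, k)
    }
    if (length(drop) == 0) break
    g$edges <- g$edges[-drop]
    # merge nodes that became pass-through (degree 2, formerly junctions)
    repeat {
      deg <- graph_degrees(g)
      two <- which(deg == 2L)
      merged <- FALSE
      for (nd in two) {
        ke <- which(vapply(g$edges, function(e)
          e$n1 == nd || e$n2 == nd, logical(1)))
        if (length(ke) != 2) next
        e1 <- g$edges[[ke[1]]]; e2 <- g$edges[[ke[2]]]
        # orient both paths to run through nd
        p1 <- if (e1$n2 == nd) e1$path else e1$path[rev(seq_len(nrow(e1$path))), , drop = FALSE]
        a <- if (e1$n2 == nd) e1$n1 else e1$n2
        p2 <- if (e2$n1 == nd) e2$path else e2$path[rev(seq_len(nrow(e2$path))), , drop = FALSE]
        b <- if (e2$n1 == nd) e2$n2 else e2$n1
        path <- rbind(p1, p2[-1, , drop = FALSE])
        g$edges[[ke[1]]] <- list(path = path, n1 = a, n2 = b,
                                 length_px = path_steps_length(path))
        g$edges <- g$edges[-ke[2]]
        merged <- TRUE
        break
      }
      if (!merged) break
    }
  }
  g
}

#' Summarise branch and junction morphometrics for one field of view
#'
#' `avg_branch_length` is the mean branch length over the field of view
#' (polylines for the ridge backend, graph edges for the skeleton backend),
#' in um; `avg_junction_number` is the junction count divided by the cell
#' count. Both are `NA` (flagged) when no branches were detected.
#'
#' @param x a `line_set` or `skeleton_graph`.
#' @param cell_count number of cells in the field of view (>= 1).
#' @param method `"ridge"` or `"skeleton"` (inferred from `x` when missing).
#' @return list with `avg_branch_length`, `avg_junction_number`,
#'   `n_branches`, `n_junctions`, `method`, `flagged`.
#' @export
summarize_morphology <- function(x, cell_count,
                                 method = c("auto", "ridge", "skeleton")) {
  method <- match.arg(method)
  if (method == "auto")
    method <- if (inherits(x, "line_set")) "ridge" else "skeleton"
  if (is.na(cell_count) || cell_count < 1) {
    message("summarize_morphology: cell_count < 1; returning NA")
    return(list(avg_branch_length = NA_real_,
                avg_junction_number = NA_real_, n_branches = 0L,
                n_junctions = 0L, method = method, flagged = TRUE))
  }
  if (method == "ridge") {
    lens <- x$lengths_um
    njunc <- nrow(x$junction_points)
  } else {
    lens <- vapply(x$edges, `[[`, numeric(1), "length_um")
    njunc <- x$n_junctions
  }
  if (length(lens) == 0) {
    return(list(avg_branch_length = NA_real_,
                avg_junction_number = NA_real_, n_branches = 0L,
                n_junctions = as.integer(njunc), method = method,
                flagged = TRUE))
  }
  list(avg_branch_length = mean(lens),
       avg_junction_number = njunc / cell_count,
       n_branches = length(lens), n_junctions = as.integer(njunc),
       method = method, flagged = FALSE)
}
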