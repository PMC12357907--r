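# Orchestration: configuration with the reference protocol's defaults,
# per-field-of-view analysis (preprocess -> segment -> bleed-through filters
# -> morphometrics), cohort runs over simulated or manifest-listed images,
# the statistics stage, and a small command-line surface.

#' Default run configuration
#'
#' Encodes the reference protocol's printed choices: Huang2 thresholds on
#' DAPI and MBP, Huang on O4; binary ops erode/open/dilate/watershed on DAPI
#' and erode/open on O4 (none on MBP); solidity < 0.7 and DAPI overlap < 60%
#' bleed-through filters on MBP; pseudo-flat-field on MBP and O4; paraboloid
#' background subtraction on O4 and DAPI; contrast enhancement on DAPI and
#' O4; alpha = 0.05. Unprinted constants (radii, saturation, minimum ROI
#' area, ridge scales) are explicit here and config-overridable.
#'
#' @return nested list of parameters.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "oligomorph_out",
    manifest = NULL,
    simulation = list(
      n_lines_per_group = 4L,
      n_fov_per_line = 6L,
      marker = "MBP",
      image_shape = c(192L, 192L),
      n_cells = 6L,
      n_free_nuclei = 4L,
      # relative SCZ lengthening; the demo default is sized by power
      # analysis so the small 2x4x6 demonstration design detects it
      # reliably (the study-anchored 8% needs ~7 lines/group)
      branch_length_effect = 0.15,
      line_rel_sd = 0.04,           # between-line lognormal scale jitter
      scene = list()                # extra scene_params overrides
    ),
    preprocess = list(
      flat_field_radius = NULL,    # NULL = image width / 3
      median_radius = 2,
      paraboloid_radius = 50,
      saturated_fraction = 0.0035,
      flat_field_channels = c("MBP", "O4"),
      background_channels = c("O4", "DAPI"),
      contrast_channels = c("DAPI", "O4")
    ),
    segment = list(
      threshold_variant = list(DAPI = "huang2", MBP = "huang2",
                               O4 = "huang"),
      binary_ops = list(DAPI = c("erode", "open", "dilate", "watershed"),
                        O4 = c("erode", "open"), MBP = character(0)),
      min_area_px = 20,
      dapi_min_area_px = 20,
      max_solidity = 0.7,
      max_overlap = 0.6,
      bleed_filter_channels = "MBP"
    ),
    morphometrics = list(
      sigma = 1.8,
      low_contrast = 20,
      high_contrast = 55,
      prune_px = 4,
      min_points = 6,
      junction_radius = 3,
      max_eigen_ratio = 0.6,
      merge_junctions_px = 4,
      methods = c("ridge", "skeleton")
    ),
    stats = list(
      alpha = 0.05,
      df_method = "between-within",
      transform = TRUE,
      variance_fraction = 0.995
    ),
    qc_overlays = TRUE
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(base[[nm]])))
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    else base[[nm]] <- user[[nm]]
  }
  base
}

#' Validate and complete a run configuration
#'
#' Fills defaults, checks ranges (cut-offs in (0,1), saturation in
#' [0, 0.5)), and — when a manifest is given — that it resolves: files
#' exist, required columns are present, no duplicate (line, fov, channel)
#' keys, and every requested marker image has a DAPI partner.
#'
#' @param config partial configuration list (or path to a YAML file).
#' @return validated config of class `run_config`.
#' @export
validate_config <- function(config = list()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- merge_config(default_config(), config)
  sg <- cfg$segment
  for (fld in c("max_solidity", "max_overlap")) {
    v <- sg[[fld]]
    if (!is.numeric(v) || v <= 0 || v >= 1)
      stop(sprintf("config error: segment$%s = %s outside (0, 1)", fld,
                   format(v)), call. = FALSE)
  }
  if (cfg$preprocess$saturated_fraction < 0 ||
      cfg$preprocess$saturated_fraction >= 0.5)
    stop("config error: preprocess$saturated_fraction outside [0, 0.5)",
         call. = FALSE)
  bad <- setdiff(unlist(sg$binary_ops),
                 c("erode", "open", "dilate", "watershed"))
  if (length(bad))
    stop("config error: unknown binary op(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(cfg$manifest)) {
    mf <- if (is.character(cfg$manifest))
      utils::read.csv(cfg$manifest, stringsAsFactors = FALSE)
    else cfg$manifest
    need <- c("path", "group", "line", "fov", "channel")
    miss <- setdiff(need, names(mf))
    if (length(miss))
      stop("config error: manifest lacks column(s): ",
           paste(miss, collapse = ", "), call. = FALSE)
    key <- paste(mf$line, mf$fov, mf$channel)
    if (anyDuplicated(key))
      stop("config error: duplicate (line, fov, channel) keys in manifest",
           call. = FALSE)
    gone <- !file.exists(mf$path)
    if (any(gone))
      stop("config error: missing image file(s): ",
           paste(utils::head(mf$path[gone], 3), collapse = ", "),
           call. = FALSE)
    markers <- setdiff(unique(mf$channel), "DAPI")
    if (length(markers) == 0)
      stop("config error: manifest has DAPI-only images but a marker ",
           "analysis was requested; missing channel(s): MBP or O4",
           call. = FALSE)
    fovs <- unique(mf[mf$channel != "DAPI", c("line", "fov")])
    for (r in seq_len(nrow(fovs))) {
      has_dapi <- any(mf$channel == "DAPI" & mf$line == fovs$line[r] &
                        mf$fov == fovs$fov[r])
      if (!has_dapi)
        stop("config error: no DAPI channel for line ", fovs$line[r],
             " fov ", fovs$fov[r], call. = FALSE)
    }
    cfg$manifest_table <- mf
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Analyse one field of view (DAPI + marker channel pair)
#'
#' Runs the preprocessing chain with channel routing, thresholds both
#' channels with the configured Huang variants, applies the configured
#' binary operations, extracts ROIs, applies the solidity and DAPI-overlap
#' bleed-through filters to the marker ROIs, and computes all four readouts
#' with both morphometric backends. Ridge polylines whose points mostly fall
#' outside the (slightly dilated) kept-cell mask are discarded, tying the
#' ridge metrics to the bleed-corrected segmentation.
#'
#' @param dapi,marker [channel_image()]s of identical shape.
#' @param cfg a validated `run_config`.
#' @return list with `record` (one-row data.frame per method), `dapi_rois`,
#'   `marker_rois_kept`, `ridge`, `skeleton`, and the preprocessed images.
#' @export
analyze_fov <- function(dapi, marker, cfg = validate_config()) {
  sg <- cfg$segment
  psz <- marker$pixel_size_um
  pre_d <- preprocess_channel(dapi, cfg$preprocess)
  pre_m <- preprocess_channel(marker, cfg$preprocess)

  th_d <- huang_threshold(pre_d, sg$threshold_variant[["DAPI"]])
  mask_d <- th_d$mask
  if (length(sg$binary_ops[["DAPI"]]))
    mask_d <- apply_binary_ops(mask_d, sg$binary_ops[["DAPI"]])
  dapi_rois <- extract_rois(mask_d, sg$dapi_min_area_px, psz)

  mch <- marker$channel
  th_m <- huang_threshold(pre_m, sg$threshold_variant[[mch]])
  mask_m <- th_m$mask
  if (length(sg$binary_ops[[mch]]))
    mask_m <- apply_binary_ops(mask_m, sg$binary_ops[[mch]])
  marker_rois <- extract_rois(mask_m, sg$min_area_px, psz)
  if (mch %in% sg$bleed_filter_channels) {
    marker_rois <- filter_by_solidity(marker_rois, sg$max_solidity)
    marker_rois <- filter_bleedthrough(marker_rois, dapi_rois,
                                       sg$max_overlap)
  }
  cell_count <- length(marker_rois)
  pct <- percent_positive(marker_rois, dapi_rois)
  cell_mask <- roi_union_mask(marker_rois, mch)
  avg_size <- average_cell_size(cell_mask, cell_count, psz)

  mm <- cfg$morphometrics
  ridge <- detect_ridges(pre_m, mm$sigma, mm$low_contrast, mm$high_contrast,
                         mm$min_points, mm$max_eigen_ratio,
                         mm$junction_radius)
  keep_mask <- bin_dilate3(bin_dilate3(cell_mask$pixels))
  inside <- vapply(ridge$polylines, function(p) {
    ii <- pmin(pmax(round(p[, 1]), 1), nrow(keep_mask))
    jj <- pmin(pmax(round(p[, 2]), 1), ncol(keep_mask))
    mean(keep_mask[cbind(ii, jj)]) > 0.5
  }, logical(1))
  ridge$polylines <- ridge$polylines[inside]
  ridge$lengths_um <- ridge$lengths_um[inside]
  if (nrow(ridge$junction_points) > 0 && any(inside)) {
    jin <- apply(ridge$junction_points, 1, function(q) {
      i <- pmin(pmax(round(q[1]), 1), nrow(keep_mask))
      j <- pmin(pmax(round(q[2]), 1), ncol(keep_mask))
      keep_mask[i, j]
    })
    ridge$junction_points <- ridge$junction_points[jin, , drop = FALSE]
  } else if (!any(inside)) {
    ridge$junction_points <- ridge$junction_points[0, , drop = FALSE]
  }
  ridge$total_length_um <- sum(ridge$lengths_um)

  skel <- skeletonize_mask(cell_mask, psz, mm$prune_px,
                           mm$merge_junctions_px)

  recs <- list()
  if ("ridge" %in% mm$methods) {
    s <- summarize_morphology(ridge, cell_count, "ridge")
    recs[["ridge"]] <- data.frame(
      marker = mch, method = "ridge", n_cells = cell_count,
      n_dapi = length(dapi_rois), percent_positive = pct,
      avg_cell_size = avg_size, avg_branch_length = s$avg_branch_length,
      avg_junction_number = s$avg_junction_number,
      n_branches = s$n_branches, stringsAsFactors = FALSE)
  }
  if ("skeleton" %in% mm$methods) {
    s <- summarize_morphology(skel, cell_count, "skeleton")
    recs[["skeleton"]] <- data.frame(
      marker = mch, method = "skeleton", n_cells = cell_count,
      n_dapi = length(dapi_rois), percent_positive = pct,
      avg_cell_size = avg_size, avg_branch_length = s$avg_branch_length,
      avg_junction_number = s$avg_junction_number,
      n_branches = s$n_branches, stringsAsFactors = FALSE)
  }
  list(record = do.call(rbind, recs), dapi_rois = dapi_rois,
       marker_rois_kept = marker_rois, ridge = ridge, skeleton = skel,
       preprocessed = list(dapi = pre_d, marker = pre_m),
       thresholds = c(dapi = th_d$threshold, marker = th_m$threshold))
}

scene_seed <- function(base_seed, index) {
  as.integer((as.numeric(base_seed) * 7919 + index * 104729) %% 2147483647)
}

simulation_scene_params <- function(cfg, group, line_scale = 1) {
  sim <- cfg$simulation
  eff <- if (group == "SCZ") 1 + sim$branch_length_effect else 1
  args <- utils::modifyList(
    list(image_shape = sim$image_shape, n_cells = sim$n_cells,
         marker = sim$marker, n_free_nuclei = sim$n_free_nuclei,
         length_scale = eff * line_scale),
    sim$scene)
  do.call(scene_params, args)
}

# deterministic per-line morphology scale (donor-line random effect)
line_scale_factor <- function(cfg, line_index) {
  sim <- cfg$simulation
  if (is.null(sim$line_rel_sd) || sim$line_rel_sd <= 0) return(1)
  set.seed(scene_seed(cfg$seed, 900000 + line_index))
  exp(stats::rnorm(1, 0, sim$line_rel_sd))
}

log_line <- function(logfile, ...) {
  msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
  if (!is.null(logfile)) cat(msg, "\n", file = logfile, append = TRUE)
  invisible(msg)
}

atomic_write_csv <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(df, tmp, row.names = FALSE)
  file.rename(tmp, path)
  invisible(path)
}

#' Run the full pipeline
#'
#' Simulation mode (no manifest): generates one ground-truthed scene per
#' (group, line, fov) cell of the configured cohort, with the configured
#' branch-length effect injected into the SCZ scenes' segment lengths.
#' Manifest mode: reads TIFF images listed in the manifest CSV. Either way,
#' every field of view is analysed with [analyze_fov()]; a failing image is
#' skipped with a logged reason and an NA record; the statistics stage then
#' runs on the tidy measurement table (ridge-backend metrics). Outputs
#' (`measurements.csv`, `stats.json`, `report.md`, `overlays/*.png`,
#' `run.log`) are written atomically under `output_dir`.
#'
#' @param config partial config (list or YAML path); see [default_config()].
#' @return invisibly, list with `records`, `table` (tidy), `stats`,
#'   `config`, `output_dir`, `n_failed`.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(cfg$output_dir, "run.log")
  cat("", file = logfile)
  log_line(logfile, "run start, seed ", cfg$seed)

  jobs <- list()
  if (!is.null(cfg$manifest)) {
    mf <- cfg$manifest_table
    fovs <- unique(mf[mf$channel != "DAPI",
                      c("group", "line", "fov", "channel")])
    for (r in seq_len(nrow(fovs))) {
      jobs[[length(jobs) + 1]] <- list(
        group = fovs$group[r], line = fovs$line[r], fov = fovs$fov[r],
        marker = fovs$channel[r],
        dapi_path = mf$path[mf$channel == "DAPI" & mf$line == fovs$line[r] &
                              mf$fov == fovs$fov[r]][1],
        marker_path = mf$path[mf$channel == fovs$channel[r] &
                                mf$line == fovs$line[r] &
                                mf$fov == fovs$fov[r]][1])
    }
  } else {
    sim <- cfg$simulation
    idx <- 0
    for (g in c("Ctrl", "SCZ")) for (li in seq_len(sim$n_lines_per_group))
      for (fv in seq_len(sim$n_fov_per_line)) {
        idx <- idx + 1
        jobs[[length(jobs) + 1]] <- list(
          group = g, line = sprintf("%s_L%02d", g, li), fov = fv,
          marker = sim$marker, scene_index = idx,
          line_index = (g == "SCZ") * sim$n_lines_per_group + li)
      }
  }

  overlay_dir <- file.path(cfg$output_dir, "overlays")
  if (isTRUE(cfg$qc_overlays))
    dir.create(overlay_dir, showWarnings = FALSE)
  records <- list()
  n_failed <- 0
  for (job in jobs) {
    t0 <- proc.time()[3]
    res <- tryCatch({
      if (!is.null(job$scene_index)) {
        sp <- simulation_scene_params(cfg, job$group,
                                      line_scale_factor(cfg,
                                                        job$line_index))
        scene <- generate_scene(sp, scene_seed(cfg$seed, job$scene_index))
        ch <- render_channels(scene)
        dapi <- ch$dapi; marker <- ch$marker
      } else {
        dp <- read_tiff(job$dapi_path)
        mp <- read_tiff(job$marker_path)
        psz <- if (!is.null(cfg$pixel_size_um)) cfg$pixel_size_um else 1
        dapi <- channel_image(dp[[1]], "DAPI", psz)
        marker <- channel_image(mp[[length(mp)]],
                                match.arg(job$marker, c("DAPI", "O4",
                                                        "MBP")), psz)
      }
      out <- analyze_fov(dapi, marker, cfg)
      if (isTRUE(cfg$qc_overlays)) {
        fn <- file.path(overlay_dir,
                        sprintf("%s_fov%02d.png", job$line, job$fov))
        tryCatch(write_overlay(out$preprocessed$marker, out$ridge,
                               out$skeleton, fn),
                 error = function(e) NULL)
      }
      out
    }, error = function(e) e)
    if (inherits(res, "error")) {
      n_failed <- n_failed + 1
      log_line(logfile, "SKIP ", job$line, " fov ", job$fov, ": ",
               conditionMessage(res))
      rec <- data.frame(marker = job$marker,
                        method = cfg$morphometrics$methods,
                        n_cells = NA_integer_, n_dapi = NA_integer_,
                        percent_positive = NA_real_,
                        avg_cell_size = NA_real_,
                        avg_branch_length = NA_real_,
                        avg_junction_number = NA_real_,
                        n_branches = NA_integer_, stringsAsFactors = FALSE)
    } else {
      rec <- res$record
      log_line(logfile, "OK ", job$line, " fov ", job$fov, " (",
               sprintf("%.2fs", proc.time()[3] - t0), ", ",
               rec$n_cells[1], " cells)")
    }
    rec <- cbind(data.frame(group = job$group, line = job$line,
                            fov = job$fov, stringsAsFactors = FALSE), rec)
    records[[length(records) + 1]] <- rec
  }
  records <- do.call(rbind, records)
  atomic_write_csv(records, file.path(cfg$output_dir, "measurements.csv"))

  table <- records_to_table(records)
  atomic_write_csv(table, file.path(cfg$output_dir,
                                    "measurements_tidy.csv"))
  st <- cfg$stats
  stats_res <- run_stats(table, alpha = st$alpha,
                         transform = isTRUE(st$transform),
                         df_method = st$df_method)
  provenance <- list(seed = cfg$seed, n_images = length(jobs),
                     n_failed = n_failed,
                     package_version = as.character(
                       utils::packageVersion("oligomorph")))
  js <- file.path(cfg$output_dir, "stats.json")
  jsonlite::write_json(list(provenance = provenance, results = stats_res),
                       js, auto_unbox = TRUE, digits = NA, force = TRUE,
                       pretty = TRUE)
  write_report(stats_res, records, provenance,
               file.path(cfg$output_dir, "report.md"))
  log_line(logfile, "run complete: ", length(jobs) - n_failed, "/",
           length(jobs), " images analysed")
  invisible(list(records = records, table = table, stats = stats_res,
                 config = cfg, output_dir = cfg$output_dir,
                 n_failed = n_failed))
}

# wide per-image records -> tidy (group, line, fov, metric, value); ridge
# metrics carry the canonical names, skeleton ones a suffix
records_to_table <- function(records) {
  out <- list()
  for (m in c("percent_positive", "avg_cell_size", "avg_branch_length",
              "avg_junction_number")) {
    r <- records[records$method == "ridge", ]
    out[[length(out) + 1]] <- data.frame(
      group = r$group, line = r$line, fov = r$fov, metric = m,
      value = r[[m]], stringsAsFactors = FALSE)
    s <- records[records$method == "skeleton", ]
    if (nrow(s) && m %in% c("avg_branch_length", "avg_junction_number"))
      out[[length(out) + 1]] <- data.frame(
        group = s$group, line = s$line, fov = s$fov,
        metric = paste0(m, "_skeleton"), value = s[[m]],
        stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

# QC overlay: preprocessed marker image in grey, ridge polylines in red,
# skeleton in green
write_overlay <- function(image, ridge, skel, path) {
  px <- as_pixel_matrix(image) / 255
  nr <- nrow(px); nc <- ncol(px)
  rgb <- array(rep(px, 3), dim = c(nr, nc, 3))
  for (p in ridge$polylines) {
    ii <- pmin(pmax(round(p[, 1]), 1), nr)
    jj <- pmin(pmax(round(p[, 2]), 1), nc)
    rgb[cbind(ii, jj, 1)] <- 1
    rgb[cbind(ii, jj, 2)] <- 0.2
    rgb[cbind(ii, jj, 3)] <- 0.2
  }
  if (!is.null(skel$skeleton)) {
    sk <- which(skel$skeleton, arr.ind = TRUE)
    if (nrow(sk)) {
      rgb[cbind(sk, 2)] <- 1
      rgb[cbind(sk, 1)] <- pmin(rgb[cbind(sk, 1)], 0.3)
    }
  }
  png::writePNG(rgb, path)
  invisible(path)
}

write_report <- function(stats_res, records, provenance, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) cat(..., "\n", file = con, sep = "")
  w("# Morphometry run report")
  w("")
  w(sprintf("Seed %s; %d images, %d failed.", provenance$seed,
            provenance$n_images, provenance$n_failed))
  w("")
  w("| metric | transform | estimate (SCZ-Ctrl) | F | df | p | t-test p | Cohen's d |")
  w("|---|---|---|---|---|---|---|---|")
  for (m in setdiff(names(stats_res), "diagnostics")) {
    r <- stats_res[[m]]
    ma <- r$mixed_anova
    tt <- r$ttest
    w(sprintf("| %s | %s | %s | %s | 1,%s | %s | %s | %s |", m,
              if (is.null(r$transform)) "identity" else r$transform$name,
              if (is.null(ma)) "-" else sprintf("%.4g", ma$estimate),
              if (is.null(ma)) "-" else sprintf("%.3f", ma$F),
              if (is.null(ma)) "-" else ma$df_den,
              if (is.null(ma)) "-" else sprintf("%.4g", ma$p_value),
              if (is.null(tt)) "-" else sprintf("%.4g", tt$p_value),
              if (is.null(tt)) "-" else sprintf("%.3g", tt$cohen_d)))
  }
  invisible(path)
}

#' Command-line entry point
#'
#' Subcommands: `simulate` (write cohort scenes as TIFF + manifest),
#' `analyze` (run image stages from a config/manifest), `stats` (statistics
#' from a tidy measurements CSV), `report` (markdown report from a stats
#' JSON), `demo` (full synthetic end-to-end study). Returns an exit status:
#' 0 success, 2 validation error, 3 partial run with skipped images.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit status, invisibly.
#' @export
run_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: oligomorph <simulate|analyze|stats|report|demo> [options]",
    "  common options: --config FILE --out DIR --seed N", sep = "\n")
  if (length(args) == 0) { cat(usage, "\n"); return(invisible(2L)) }
  cmd <- args[1]
  opt <- list(config = NULL, out = "oligomorph_out", seed = NULL,
              measurements = NULL, stats = NULL)
  i <- 2
  while (i <= length(args)) {
    key <- sub("^--", "", args[i])
    if (!key %in% names(opt) || i == length(args)) {
      cat("unknown or incomplete option: ", args[i], "\n", usage, "\n")
      return(invisible(2L))
    }
    opt[[key]] <- args[i + 1]
    i <- i + 2
  }
  cfg <- tryCatch({
    base <- if (!is.null(opt$config)) yaml::read_yaml(opt$config) else list()
    base$output_dir <- opt$out
    if (!is.null(opt$seed)) base$seed <- as.integer(opt$seed)
    validate_config(base)
  }, error = function(e) e)
  if (inherits(cfg, "error")) {
    cat("validation error: ", conditionMessage(cfg), "\n")
    return(invisible(2L))
  }
  status <- 0L
  if (cmd == "simulate") {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    sim <- cfg$simulation
    rows <- list(); idx <- 0
    for (g in c("Ctrl", "SCZ")) for (li in seq_len(sim$n_lines_per_group))
      for (fv in seq_len(sim$n_fov_per_line)) {
        idx <- idx + 1
        lidx <- (g == "SCZ") * sim$n_lines_per_group + li
        sp <- simulation_scene_params(cfg, g, line_scale_factor(cfg, lidx))
        scene <- generate_scene(sp, scene_seed(cfg$seed, idx))
        line <- sprintf("%s_L%02d", g, li)
        fn <- file.path(cfg$output_dir,
                        sprintf("%s_fov%02d.tif", line, fv))
        write_scene(scene, fn)
        rows[[length(rows) + 1]] <- data.frame(
          path = fn, group = g, line = line, fov = fv,
          channel = c("DAPI", sim$marker), page = c(1, 2))
      }
    atomic_write_csv(do.call(rbind, rows),
                     file.path(cfg$output_dir, "manifest.csv"))
    cat("wrote ", idx, " scenes + manifest.csv to ", cfg$output_dir, "\n")
  } else if (cmd == "analyze" || cmd == "demo") {
    res <- run_pipeline(cfg)
    cat("analysed ", nrow(res$records) / 2, " images (",
        res$n_failed, " failed); outputs in ", res$output_dir, "\n",
        sep = "")
    for (m in setdiff(names(res$stats), "diagnostics")) {
      ma <- res$stats[[m]]$mixed_anova
      if (!is.null(ma))
        cat(sprintf("  %-28s estimate %+.4g  F(1,%d)=%.2f  p=%.4g\n", m,
                    ma$estimate, ma$df_den, ma$F, ma$p_value))
    }
    if (res$n_failed > 0) status <- 3L
  } else if (cmd == "stats") {
    if (is.null(opt$measurements)) {
      cat("stats requires --measurements FILE\n")
      return(invisible(2L))
    }
    tab <- read_measurements(opt$measurements)
    st <- run_stats(tab, alpha = cfg$stats$alpha,
                    transform = isTRUE(cfg$stats$transform),
                    df_method = cfg$stats$df_method)
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    jsonlite::write_json(st, file.path(cfg$output_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE,
                         pretty = TRUE)
    cat("wrote stats.json to ", cfg$output_dir, "\n")
  } else if (cmd == "report") {
    if (is.null(opt$stats)) {
      cat("report requires --stats FILE\n")
      return(invisible(2L))
    }
    st <- jsonlite::read_json(opt$stats, simplifyVector = TRUE)
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_report(st$results, NULL,
                 st$provenance, file.path(cfg$output_dir, "report.md"))
    cat("wrote report.md to ", cfg$output_dir, "\n")
  } else {
    cat(usage, "\n")
    status <- 2L
  }
  invisible(status)
}
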