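# Hierarchical statistics: transform-to-normality selection scored by the
# Shapiro-Wilk statistic, distributional diagnostics (Shapiro-Wilk, Levene,
# Box's M, 3xIQR extreme outliers), a random-intercept mixed-effects ANOVA
# for donor lines nested in diagnostic groups, line-level t-tests with
# Cohen's d, and the simpleM effective-number-of-tests correction.

# --- transform families -----------------------------------------------------

yeo_johnson <- function(x, lambda) {
  out <- numeric(length(x))
  pos <- x >= 0
  if (abs(lambda) > 1e-8) out[pos] <- ((x[pos] + 1)^lambda - 1) / lambda
  else out[pos] <- log(x[pos] + 1)
  l2 <- 2 - lambda
  if (abs(l2) > 1e-8) out[!pos] <- -((-x[!pos] + 1)^l2 - 1) / l2
  else out[!pos] <- -log(-x[!pos] + 1)
  out
}

yeo_johnson_inv <- function(y, lambda) {
  out <- numeric(length(y))
  pos <- y >= 0
  if (abs(lambda) > 1e-8) out[pos] <- (y[pos] * lambda + 1)^(1 / lambda) - 1
  else out[pos] <- exp(y[pos]) - 1
  l2 <- 2 - lambda
  if (abs(l2) > 1e-8) out[!pos] <- 1 - (1 - y[!pos] * l2)^(1 / l2)
  else out[!pos] <- 1 - exp(-y[!pos])
  out
}

box_cox <- function(x, lambda) {
  if (abs(lambda) > 1e-8) (x^lambda - 1) / lambda else log(x)
}

box_cox_inv <- function(y, lambda) {
  if (abs(lambda) > 1e-8) (y * lambda + 1)^(1 / lambda) else exp(y)
}

sw_w <- function(x) {
  if (length(unique(x)) < 3) return(NA_real_)
  n <- length(x)
  if (n > 5000) x <- sort(x)[round(seq(1, n, length.out = 5000))]
  tryCatch(stats::shapiro.test(x)$statistic[[1]],
           error = function(e) NA_real_)
}

best_lambda <- function(x, family) {
  grid <- seq(-2, 2, by = 0.1)
  ws <- vapply(grid, function(l) {
    y <- if (family == "box-cox") box_cox(x, l) else yeo_johnson(x, l)
    if (any(!is.finite(y))) return(NA_real_)
    sw_w(y)
  }, numeric(1))
  if (all(is.na(ws))) return(NULL)
  grid[which.max(ws)]
}

#' Select the transform that best normalises a sample
#'
#' Fits each candidate family — identity, `sqrt(x + a)` (with
#' `a = max(0, 1 - min(x))`), `asinh`, Box-Cox (positive data only),
#' Yeo-Johnson, and orderNorm (rank-based inverse normal) — and returns the
#' one whose transformed sample has the largest Shapiro-Wilk W. Power-family
#' parameters are chosen on the same criterion over a lambda grid. Ties (W
#' within 1e-4) go to the simplest family, in the order identity <
#' sqrt/asinh < Box-Cox/Yeo-Johnson < orderNorm. All fitted transforms are
#' strictly increasing on the data range, so group comparisons keep their
#' direction.
#'
#' @param values numeric vector (>= 4 finite values).
#' @return a `transform_result`: `transform`, `parameters`, `transformed`,
#'   `w_before`, `w_after`, `fun` / `inverse` (closures), `degenerate`.
#' @export
select_transform <- function(values) {
  x <- values[is.finite(values)]
  if (length(x) < 4) stop(">= 4 finite values required", call. = FALSE)
  if (length(unique(x)) == 1) {
    res <- list(transform = "identity", parameters = list(),
                transformed = x, w_before = NA_real_, w_after = NA_real_,
                fun = identity, inverse = identity, degenerate = TRUE)
    class(res) <- "transform_result"
    return(res)
  }
  w0 <- sw_w(x)
  cands <- list(list(name = "identity", rank = 0, fun = identity,
                     inverse = identity, parameters = list()))
  a <- max(0, 1 - min(x))
  cands[[length(cands) + 1]] <- list(
    name = "sqrt_shift", rank = 1,
    fun = function(v) sqrt(v + a),
    inverse = function(y) y^2 - a,
    parameters = list(a = a))
  cands[[length(cands) + 1]] <- list(
    name = "asinh", rank = 1, fun = asinh, inverse = sinh,
    parameters = list())
  if (min(x) > 0) {
    lam <- best_lambda(x, "box-cox")
    if (!is.null(lam))
      cands[[length(cands) + 1]] <- list(
        name = "box-cox", rank = 2,
        fun = local({l <- lam; function(v) box_cox(v, l)}),
        inverse = local({l <- lam; function(y) box_cox_inv(y, l)}),
        parameters = list(lambda = lam))
  }
  lam <- best_lambda(x, "yeo-johnson")
  if (!is.null(lam))
    cands[[length(cands) + 1]] <- list(
      name = "yeo-johnson", rank = 2,
      fun = local({l <- lam; function(v) yeo_johnson(v, l)}),
      inverse = local({l <- lam; function(y) yeo_johnson_inv(y, l)}),
      parameters = list(lambda = lam))
  # orderNorm: rank-based inverse normal; inverse by interpolation on the
  # training data (exact on training ranks)
  xs <- sort(x)
  n <- length(x)
  zs <- stats::qnorm((seq_len(n) - 0.5) / n)
  on_fun <- function(v) {
    r <- stats::approx(xs, zs, xout = v, rule = 2, ties = "ordered")$y
    r
  }
  on_inv <- function(y) stats::approx(zs, xs, xout = y, rule = 2,
                                      ties = "ordered")$y
  cands[[length(cands) + 1]] <- list(
    name = "ordernorm", rank = 3, fun = on_fun, inverse = on_inv,
    parameters = list(n = n))
  ws <- vapply(cands, function(cc) {
    y <- cc$fun(x)
    if (any(!is.finite(y))) return(NA_real_)
    sw_w(y)
  }, numeric(1))
  ranks <- vapply(cands, `[[`, numeric(1), "rank")
  if (all(is.na(ws))) {
    # normality cannot be scored (e.g. fewer than 3 distinct values):
    # fall back to the identity, flagged degenerate
    res <- list(transform = "identity", parameters = list(),
                transformed = x, w_before = w0, w_after = w0,
                fun = identity, inverse = identity, degenerate = TRUE)
    class(res) <- "transform_result"
    return(res)
  }
  best_w <- max(ws, na.rm = TRUE)
  tied <- which(!is.na(ws) & ws >= best_w - 1e-4)
  pick <- tied[order(ranks[tied], -ws[tied])][1]
  cc <- cands[[pick]]
  res <- list(transform = cc$name, parameters = cc$parameters,
              transformed = cc$fun(x), w_before = w0, w_after = ws[pick],
              fun = cc$fun, inverse = cc$inverse, degenerate = FALSE)
  class(res) <- "transform_result"
  res
}

#' @export
print.transform_result <- function(x, ...) {
  cat(sprintf("<transform_result> %s  (W %.4f -> %.4f)\n", x$transform,
              x$w_before, x$w_after))
  if (length(x$parameters))
    cat("  parameters:", paste(names(x$parameters), "=",
                               vapply(x$parameters, format, character(1)),
                               collapse = ", "), "\n")
  invisible(x)
}

# --- diagnostics ------------------------------------------------------------

#' Levene's test (median-centred / Brown-Forsythe)
#'
#' One-way ANOVA on absolute deviations from the group medians.
#'
#' @param values numeric vector.
#' @param groups grouping factor.
#' @return list with `statistic`, `df`, `p_value`.
#' @export
levene_test <- function(values, groups) {
  g <- factor(groups)
  z <- abs(values - stats::ave(values, g, FUN = stats::median))
  k <- nlevels(g); n <- length(z)
  zm <- tapply(z, g, mean); nn <- tapply(z, g, length)
  zbar <- mean(z)
  num <- sum(nn * (zm - zbar)^2) / (k - 1)
  den <- sum((z - stats::ave(z, g, FUN = mean))^2) / (n - k)
  f <- if (den > 0) num / den else 0
  list(statistic = f, df = c(k - 1, n - k),
       p_value = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

#' Box's M test for homogeneity of covariance matrices
#'
#' Chi-square approximation; requires each group to have more observations
#' than variables.
#'
#' @param data numeric matrix (rows = samples, cols = variables).
#' @param groups grouping factor.
#' @return list with `statistic`, `df`, `p_value`, or `NULL` when not
#'   estimable.
#' @export
box_m_test <- function(data, groups) {
  g <- factor(groups)
  k <- nlevels(g); p <- ncol(data)
  ns <- tabulate(g)
  if (any(ns <= p)) return(NULL)
  covs <- lapply(levels(g), function(l)
    stats::cov(data[g == l, , drop = FALSE]))
  vs <- ns - 1
  Sp <- Reduce(`+`, Map(function(S, v) S * v, covs, vs)) / sum(vs)
  lds <- vapply(covs, function(S) determinant(S, logarithm = TRUE)$modulus,
                numeric(1))
  ldp <- determinant(Sp, logarithm = TRUE)$modulus
  if (!all(is.finite(lds)) || !is.finite(ldp)) return(NULL)
  M <- sum(vs) * ldp - sum(vs * lds)
  c1 <- (2 * p^2 + 3 * p - 1) / (6 * (p + 1) * (k - 1)) *
    (sum(1 / vs) - 1 / sum(vs))
  stat <- M * (1 - c1)
  df <- p * (p + 1) * (k - 1) / 2
  list(statistic = as.numeric(stat), df = df,
       p_value = stats::pchisq(as.numeric(stat), df, lower.tail = FALSE))
}

#' Distributional diagnostics per metric
#'
#' Per metric: Shapiro-Wilk normality p, Levene (median-centred)
#' equality-of-variance p across groups, and extreme-outlier flags (values
#' beyond 3 x IQR outside the quartiles). When two or more metrics can be
#' assessed jointly (complete fields of view), Box's M tests covariance
#' homogeneity.
#'
#' @param table a measurement table (`group`, `line`, `fov`, `metric`,
#'   `value`).
#' @return list with per-metric data.frame `metrics`, `outliers`
#'   data.frame, and `box_m` (or NULL).
#' @export
diagnostics <- function(table) {
  if (length(unique(table$group)) < 2)
    stop(">= 2 groups required", call. = FALSE)
  mets <- unique(table$metric)
  rows <- list(); outl <- list()
  for (m in mets) {
    d <- table[table$metric == m & is.finite(table$value), ]
    if (nrow(d) < 3) {
      message("diagnostics: metric ", m, " has < 3 values; skipped")
      next
    }
    sw <- tryCatch(stats::shapiro.test(d$value)$p.value,
                   error = function(e) NA_real_)
    lv <- levene_test(d$value, d$group)
    q <- stats::quantile(d$value, c(0.25, 0.75), names = FALSE)
    iqr <- q[2] - q[1]
    ext <- d$value > q[2] + 3 * iqr | d$value < q[1] - 3 * iqr
    rows[[m]] <- data.frame(metric = m, n = nrow(d), shapiro_p = sw,
                            levene_p = lv$p_value,
                            n_extreme_outliers = sum(ext))
    if (any(ext))
      outl[[m]] <- cbind(d[ext, c("group", "line", "fov", "metric",
                                  "value")])
  }
  bm <- NULL
  if (length(mets) >= 2) {
    wide <- stats::reshape(table[, c("group", "line", "fov", "metric",
                                     "value")],
                           idvar = c("group", "line", "fov"),
                           timevar = "metric", direction = "wide")
    cols <- grep("^value\\.", names(wide))
    cc <- stats::complete.cases(wide[, cols])
    if (sum(cc) > length(cols) + 2)
      bm <- box_m_test(as.matrix(wide[cc, cols]), wide$group[cc])
  }
  list(metrics = do.call(rbind, rows),
       outliers = if (length(outl)) do.call(rbind, outl) else NULL,
       box_m = bm)
}

# --- mixed-effects ANOVA ----------------------------------------------------

#' Mixed-effects ANOVA with donor line as a random intercept
#'
#' Fits `value ~ group + (1 | line)` by REML (fields of view nested in donor
#' lines nested in groups) and tests the group contrast with an F test whose
#' denominator degrees of freedom follow the between-within convention,
#' `df = n_lines - 2`. A boundary (singular) fit with zero line variance is
#' returned with `singular = TRUE`, never an error.
#'
#' @param table measurement table.
#' @param metric which metric to analyse.
#' @param df_method `"between-within"` (default) or `"residual"` (the naive
#'   `n_obs - 2`, documented alternative).
#' @return a `mixed_anova_result`: `estimate` (SCZ - Ctrl), `se`, `F`,
#'   `df_num`, `df_den`, `p_value`, `var_line`, `var_resid`, `singular`,
#'   `n_lines`, `n_obs`.
#' @export
fit_mixed_anova <- function(table, metric,
                            df_method = c("between-within", "residual")) {
  df_method <- match.arg(df_method)
  d <- table[table$metric == metric & is.finite(table$value), ]
  lines_per_group <- tapply(d$line, d$group, function(x)
    length(unique(x)))
  if (length(lines_per_group) < 2 || any(lines_per_group < 2))
    stop(">= 2 lines per group required", call. = FALSE)
  d$group <- factor(d$group)
  n_lines <- length(unique(d$line))
  fit <- suppressWarnings(suppressMessages(
    lme4::lmer(value ~ group + (1 | line), data = d, REML = TRUE)))
  singular <- lme4::isSingular(fit, tol = 1e-5)
  co <- lme4::fixef(fit)
  vc <- as.data.frame(lme4::VarCorr(fit))
  var_line <- vc$vcov[vc$grp == "line"][1]
  var_resid <- vc$vcov[vc$grp == "Residual"][1]
  se <- sqrt(diag(as.matrix(stats::vcov(fit))))[2]
  est <- co[[2]]
  Fst <- (est / se)^2
  df_den <- if (df_method == "between-within") n_lines - 2 else
    nrow(d) - 2
  p <- stats::pf(Fst, 1, df_den, lower.tail = FALSE)
  res <- list(metric = metric, estimate = est, se = se, F = Fst,
              df_num = 1, df_den = df_den, p_value = p,
              var_line = var_line, var_resid = var_resid,
              singular = singular, n_lines = n_lines, n_obs = nrow(d),
              contrast = paste(levels(d$group)[2], "-", levels(d$group)[1]))
  class(res) <- "mixed_anova_result"
  res
}

#' @export
print.mixed_anova_result <- function(x, ...) {
  cat(sprintf(
    "<mixed_anova> %s: %s = %.4g (SE %.3g), F(1,%d) = %.3f, p = %.4g\n",
    x$metric, x$contrast, x$estimate, x$se, x$df_den, x$F, x$p_value))
  cat(sprintf("  var(line) = %.4g, var(resid) = %.4g%s\n", x$var_line,
              x$var_resid, if (x$singular) "  [boundary fit]" else ""))
  invisible(x)
}

#' Group-level t-test and Cohen's d on line means
#'
#' Collapses fields of view to one mean per donor line, then compares groups
#' with a two-sample pooled-variance t-test; Cohen's d is the pooled-SD
#' standardised mean difference of the line means.
#'
#' @param table measurement table.
#' @param metric metric name.
#' @return list with `t`, `df`, `p_value`, `cohen_d`, `mean_diff`
#'   (SCZ - Ctrl), `n_lines`.
#' @export
group_ttest_cohend <- function(table, metric) {
  d <- table[table$metric == metric & is.finite(table$value), ]
  lm_tab <- stats::aggregate(value ~ group + line, d, mean)
  gs <- split(lm_tab$value, lm_tab$group)
  if (length(gs) != 2 || any(vapply(gs, length, integer(1)) < 2))
    stop("each group needs >= 2 lines", call. = FALSE)
  # SCZ - Ctrl orientation when those labels are present
  nm <- names(gs)
  x2 <- if ("SCZ" %in% nm) gs[["SCZ"]] else gs[[2]]
  x1 <- if ("Ctrl" %in% nm) gs[["Ctrl"]] else gs[[1]]
  n1 <- length(x1); n2 <- length(x2)
  sp2 <- ((n1 - 1) * stats::var(x1) + (n2 - 1) * stats::var(x2)) /
    (n1 + n2 - 2)
  md <- mean(x2) - mean(x1)
  if (sp2 <= 0) {
    t <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    dvl <- if (md == 0) 0 else sign(md) * Inf
  } else {
    t <- md / sqrt(sp2 * (1 / n1 + 1 / n2))
    p <- 2 * stats::pt(-abs(t), n1 + n2 - 2)
    dvl <- md / sqrt(sp2)
  }
  list(t = t, df = n1 + n2 - 2, p_value = p, cohen_d = dvl,
       mean_diff = md, n_lines = c(n1, n2))
}

#' Effective number of tests (simpleM)
#'
#' Eigen-decomposes the correlation matrix of the test statistics and takes
#' the smallest number of leading eigenvalues explaining at least
#' `variance_fraction` of the total variance; the adjusted significance
#' level is `alpha / meff`.
#'
#' @param statistic_matrix samples x tests numeric matrix.
#' @param variance_fraction fraction of variance to capture (default 0.995).
#' @param alpha nominal significance level.
#' @return a `meff_result`: `m`, `eigenvalues`, `meff`, `adjusted_alpha`.
#' @export
effective_tests_simplem <- function(statistic_matrix,
                                    variance_fraction = 0.995,
                                    alpha = 0.05) {
  x <- as.matrix(statistic_matrix)
  if (ncol(x) < 2) stop(">= 2 tests required", call. = FALSE)
  if (nrow(x) < 3) stop(">= 3 samples required", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warning("removing ", sum(sds == 0), " constant column(s)")
    x <- x[, sds > 0, drop = FALSE]
    if (ncol(x) < 2) stop("fewer than 2 non-constant tests", call. = FALSE)
  }
  cm <- stats::cor(x)
  ev <- eigen(cm, symmetric = TRUE, only.values = TRUE)$values
  ev <- pmax(ev, 0)
  cum <- cumsum(ev) / sum(ev)
  meff <- which(cum >= variance_fraction)[1]
  res <- list(m = ncol(x), eigenvalues = ev, meff = as.integer(meff),
              adjusted_alpha = alpha / meff)
  class(res) <- "meff_result"
  res
}

#' @export
print.meff_result <- function(x, ...) {
  cat(sprintf("<meff_result> m = %d tests, meff = %d, adjusted alpha = %.4g\n",
              x$m, x$meff, x$adjusted_alpha))
  invisible(x)
}

#' Full statistics stage for a measurement table
#'
#' Per metric: transform selection on the pooled values, diagnostics,
#' mixed-effects ANOVA on the transformed values, and the line-level
#' t-test / Cohen's d (also on transformed values). The monotone transforms
#' preserve the sign of group differences.
#'
#' @param table measurement table.
#' @param alpha significance level.
#' @param transform apply transform-to-normality selection first?
#' @param df_method passed to [fit_mixed_anova()].
#' @return a named list per metric with `transform`, `mixed_anova`,
#'   `ttest`, plus a `diagnostics` element.
#' @export
run_stats <- function(table, alpha = 0.05, transform = TRUE,
                      df_method = "between-within") {
  mets <- unique(table$metric)
  out <- list()
  for (m in mets) {
    d <- table[table$metric == m & is.finite(table$value), ]
    tr <- NULL
    if (transform && nrow(d) >= 4 && length(unique(d$value)) > 1) {
      tr <- select_transform(d$value)
      d$value <- tr$fun(d$value)
    }
    ma <- tryCatch(fit_mixed_anova(d, m, df_method = df_method),
                   error = function(e) NULL)
    tt <- tryCatch(group_ttest_cohend(d, m), error = function(e) NULL)
    out[[m]] <- list(
      transform = if (is.null(tr)) NULL else
        list(name = tr$transform, parameters = tr$parameters,
             w_before = tr$w_before, w_after = tr$w_after),
      mixed_anova = if (is.null(ma)) NULL else unclass(ma),
      ttest = tt,
      significant = if (is.null(ma)) NA else ma$p_value < alpha)
  }
  out$diagnostics <- tryCatch(
    lapply(diagnostics(table), function(z)
      if (is.data.frame(z)) z else z),
    error = function(e) NULL)
  out
}
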