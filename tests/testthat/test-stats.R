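# Transform selection, diagnostics, mixed-effects ANOVA, effect sizes,
# simpleM multiplicity correction

test_that("transform selection never harms an already-normal sample", {
  set.seed(101)
  x <- rnorm(200)
  tr <- select_transform(x)
  w_id <- shapiro.test(x)$statistic[[1]]
  expect_gte(tr$w_after, w_id - 0.01)
})

test_that("lognormal samples get a log-like or rank transform", {
  set.seed(102)
  x <- rlnorm(200)
  tr <- select_transform(x)
  expect_true(tr$transform %in% c("box-cox", "yeo-johnson", "ordernorm"))
  if (tr$transform == "box-cox")
    expect_lt(abs(tr$parameters$lambda), 0.35)
  expect_gt(tr$w_after, tr$w_before)
})

test_that("all candidate transforms are strictly increasing and invertible", {
  set.seed(103)
  for (x in list(rlnorm(80), rnorm(60, 5, 2), rexp(100) - 0.3)) {
    tr <- select_transform(x)
    xs <- sort(x)
    y <- tr$fun(xs)
    expect_true(all(diff(y) > -1e-12))
    if (tr$transform != "ordernorm") {
      expect_equal(tr$inverse(tr$fun(x)), x, tolerance = 1e-7)
    } else {
      # rank-based: exact on training data up to interpolation ties
      expect_equal(tr$inverse(tr$fun(xs)), xs, tolerance = 1e-6)
    }
  }
  expect_equal(asinh(0), 0)
  expect_error(select_transform(c(1, 2, NA)), ">= 4")
  expect_true(select_transform(rep(3, 10))$degenerate)
})

test_that("levene statistic is 0 for groups with identical spread pattern", {
  v <- c(1, 2, 3, 1, 2, 3)
  g <- rep(c("a", "b"), each = 3)
  lt <- levene_test(v, g)
  expect_equal(lt$statistic, 0)
  expect_equal(lt$p_value, 1)
})

test_that("levene type-I error is calibrated near 5%", {
  reps <- 400
  set.seed(104)
  rej <- 0
  for (k in seq_len(reps)) {
    v <- rnorm(60)
    g <- rep(c("a", "b"), each = 30)
    if (levene_test(v, g)$p_value < 0.05) rej <- rej + 1
  }
  p_hat <- rej / reps
  mc_se <- sqrt(0.05 * 0.95 / reps)
  expect_lt(abs(p_hat - 0.05), 3 * mc_se)
})

test_that("diagnostics flags 3xIQR extreme outliers and runs Box's M", {
  set.seed(105)
  tab <- simulate_measurements(cohort_design(n_lines_per_group = 4,
                                             n_fov_per_line = 8, seed = 9))
  # inject a value at Q3 + 3.5 IQR for one metric
  d <- tab$value[tab$metric == "avg_branch_length"]
  q <- quantile(d, c(0.25, 0.75)); iqr <- q[2] - q[1]
  tab$value[which(tab$metric == "avg_branch_length")[1]] <-
    q[2] + 3.5 * iqr
  rep <- diagnostics(tab)
  row <- rep$metrics[rep$metrics$metric == "avg_branch_length", ]
  expect_gte(row$n_extreme_outliers, 1)
  expect_true(all(c("shapiro_p", "levene_p") %in% names(rep$metrics)))
  expect_false(is.null(rep$box_m))
  expect_gt(rep$box_m$p_value, 0)
  expect_error(diagnostics(tab[tab$group == "Ctrl", ]), "2 groups")
})

test_that("mixed ANOVA reduces to one-way ANOVA when line variance is 0", {
  set.seed(106)
  # balanced design, all line effects identical (zero line variance)
  tab <- simulate_measurements(cohort_design(
    n_lines_per_group = 5, n_fov_per_line = 6, metrics = "m",
    grand_mean = 1, group_effect = 0.4, line_sd = 0, fov_sd = 0.2,
    seed = 11))
  ma <- quiet(fit_mixed_anova(tab, "m"))
  ow <- anova(lm(value ~ group, tab))
  expect_lt(abs(ma$F - ow$`F value`[1]) / ow$`F value`[1], 0.05)
  expect_true(ma$singular)
  expect_equal(ma$df_den, 8)   # 10 lines - 2
  # estimate is SCZ - Ctrl
  expect_gt(ma$estimate, 0)
})

test_that("mixed ANOVA requires two lines per group", {
  tab <- simulate_measurements(cohort_design(n_lines_per_group = 2,
                                             n_fov_per_line = 4, seed = 3))
  sub <- tab[tab$line != "Ctrl_L01", ]
  expect_error(quiet(fit_mixed_anova(sub, "avg_branch_length")),
               "2 lines")
})

test_that("group t-test and Cohen's d match the closed form", {
  mk <- function(vals, g) data.frame(group = g, line = paste0(g, seq_along(vals)),
                                     fov = 1, metric = "m", value = vals)
  tab <- rbind(mk(c(0.1, 0.2, 0.3, 0.4), "Ctrl"),
               mk(c(0.5, 0.6, 0.7, 0.8), "SCZ"))
  tt <- group_ttest_cohend(tab, "m")
  sp <- sqrt((3 * var(c(0.1, 0.2, 0.3, 0.4)) +
                3 * var(c(0.5, 0.6, 0.7, 0.8))) / 6)
  expect_equal(tt$mean_diff, 0.4)
  expect_equal(tt$cohen_d, 0.4 / sp)
  expect_equal(tt$df, 6)
  expect_equal(tt$t, 0.4 / (sp * sqrt(1 / 4 + 1 / 4)))
  # identical line means: d = 0, p = 1
  tab2 <- rbind(mk(c(1, 1, 1), "Ctrl"), mk(c(1, 1, 1), "SCZ"))
  tt2 <- group_ttest_cohend(tab2, "m")
  expect_equal(tt2$cohen_d, 0)
  expect_equal(tt2$p_value, 1)
  # near-separation: enormous positive d
  set.seed(107)
  tab3 <- rbind(mk(rnorm(3, 0, 1e-9), "Ctrl"), mk(1 + rnorm(3, 0, 1e-9), "SCZ"))
  tt3 <- group_ttest_cohend(tab3, "m")
  expect_gt(tt3$cohen_d, 1e5)
  expect_error(group_ttest_cohend(mk(1:3, "Ctrl"), "m"), "2 lines")
})

test_that("fov means collapse before the line-level t-test", {
  # unbalanced fov counts must not weight lines unevenly
  tab <- data.frame(
    group = c(rep("Ctrl", 4), rep("SCZ", 4)),
    line = c("c1", "c1", "c1", "c2", "s1", "s1", "s2", "s2"),
    fov = c(1, 2, 3, 1, 1, 2, 1, 2), metric = "m",
    value = c(0, 0, 3, 2, 5, 7, 4, 4))
  tt <- group_ttest_cohend(tab, "m")
  # line means: Ctrl {1, 2}, SCZ {6, 4}
  expect_equal(tt$mean_diff, 5 - 1.5)
})

test_that("simpleM matches brute-force eigen oracles", {
  set.seed(108)
  n <- 4000
  # 10 independent columns -> meff 10
  x <- matrix(rnorm(n * 10), n, 10)
  m <- effective_tests_simplem(x)
  expect_equal(m$meff, 10L)
  expect_equal(m$adjusted_alpha, 0.005)
  expect_equal(sum(m$eigenvalues), 10, tolerance = 1e-6)
  # 10 identical columns -> meff 1
  x1 <- matrix(rep(rnorm(n), 10), n, 10)
  expect_equal(effective_tests_simplem(x1)$meff, 1L)
  # two independent blocks of 5 perfectly correlated columns -> meff 2,
  # cross-checked against the analytic block spectrum (5, 5, 0, ...)
  b1 <- rnorm(n); b2 <- rnorm(n)
  xb <- cbind(matrix(rep(b1, 5), n, 5), matrix(rep(b2, 5), n, 5))
  mb <- effective_tests_simplem(xb)
  expect_equal(mb$meff, 2L)
  block_cor <- diag(2) %x% matrix(1, 5, 5)
  ev_oracle <- sort(eigen(block_cor, symmetric = TRUE)$values,
                    decreasing = TRUE)
  # eigenvalues match the analytic block spectrum up to the finite-sample
  # cross-block correlation (|rho_hat| ~ 1/sqrt(n))
  expect_equal(sort(mb$eigenvalues, decreasing = TRUE), ev_oracle,
               tolerance = 0.02)
  # constant column removed with warning
  xc <- cbind(x, 5)
  expect_warning(mc <- effective_tests_simplem(xc), "constant")
  expect_equal(mc$m, 10L)
  expect_error(effective_tests_simplem(x[, 1, drop = FALSE]), "2 tests")
  expect_error(effective_tests_simplem(x[1:2, ]), "3 samples")
})

test_that("simpleM is bounded and monotone in exchangeable correlation", {
  set.seed(109)
  n <- 600; p <- 8
  meffs <- vapply(c(0, 0.3, 0.6, 0.9), function(rho) {
    z <- rnorm(n)
    x <- sqrt(rho) * matrix(rep(z, p), n, p) +
      sqrt(1 - rho) * matrix(rnorm(n * p), n, p)
    effective_tests_simplem(x)$meff
  }, integer(1))
  expect_true(all(meffs >= 1 & meffs <= p))
  expect_true(all(diff(meffs) <= 0))
})

test_that("run_stats assembles per-metric results with monotone transforms", {
  tab <- simulate_measurements(cohort_design(n_lines_per_group = 4,
                                             n_fov_per_line = 6, seed = 21))
  res <- quiet(run_stats(tab))
  for (m in c("avg_branch_length", "avg_junction_number")) {
    expect_false(is.null(res[[m]]$mixed_anova))
    expect_false(is.null(res[[m]]$ttest))
    # monotone transform keeps the direction of the group difference
    raw_diff <- mean(tab$value[tab$metric == m & tab$group == "SCZ"]) -
      mean(tab$value[tab$metric == m & tab$group == "Ctrl"])
    expect_equal(sign(res[[m]]$mixed_anova$estimate), sign(raw_diff))
  }
})
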