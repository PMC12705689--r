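test_that("noise-free planted effects are fitted exactly", {
  set.seed(1)
  tab <- gaussian_trial(10, resid_sd = 0, baseline_slope = 0)
  eff <- c(LCPUFA = -1.46, HND = -1.76, UC = 0)
  tab$y_m12 <- tab$y_m0 + eff[tab$arm]
  # a zero-residual fixture makes summary.lm warn about the perfect fit
  ct <- suppressWarnings(fit_ancova(tab, spec_y))$contrasts
  expect_equal(ct$estimate[ct$label == "HND vs UC"], -1.76,
               tolerance = 1e-10)
  expect_equal(ct$estimate[ct$label == "LCPUFA vs UC"], -1.46,
               tolerance = 1e-10)
  expect_equal(ct$estimate[ct$label == "LCPUFA vs HND"], 0.30,
               tolerance = 1e-10)
})

test_that("ANCOVA matches a brute-force normal-equations solve", {
  set.seed(2)
  tab <- data.frame(id = 1:6, arm = rep(c("LCPUFA", "HND", "UC"), 2),
                    sex = c("man", "woman", "man", "woman", "man", "woman"),
                    t2d = c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE),
                    y_m0 = c(5, 7, 6, 9, 4, 8))
  tab$y_m12 <- tab$y_m0 + c(1.2, -0.5, 0.3, 2.0, -1.1, 0.7)
  ft <- fit_ancova(tab, spec_y)
  y <- tab$y_m12 - tab$y_m0
  X <- cbind(1, tab$arm == "LCPUFA", tab$arm == "HND", tab$y_m0,
             tab$sex == "woman", tab$t2d)
  beta <- solve(t(X) %*% X, t(X) %*% y)
  # same parametrization: reference UC, then arm coefficients
  expect_equal(unname(ft$arm_coefs["LCPUFA"]), beta[2], tolerance = 1e-10)
  expect_equal(unname(ft$arm_coefs["HND"]), beta[3], tolerance = 1e-10)
})

test_that("arm contrasts are invariant to covariate centering and transitive", {
  set.seed(3)
  tab <- gaussian_trial(30)
  ct1 <- fit_ancova(tab, spec_y)$contrasts
  tab2 <- tab
  tab2$y_m0 <- tab2$y_m0 - mean(tab2$y_m0)
  tab2$y_m12 <- tab2$y_m12 - mean(tab$y_m0)
  ct2 <- fit_ancova(tab2, spec_y)$contrasts
  expect_equal(ct1$estimate, ct2$estimate, tolerance = 1e-10)
  # transitivity within the full three-arm fit
  e <- setNames(ct1$estimate, ct1$label)
  expect_equal(unname(e["LCPUFA vs UC"] - e["HND vs UC"]),
               unname(e["LCPUFA vs HND"]), tolerance = 1e-8)
  # rank deficiency is reported by name
  tab$dup <- tab$y_m0
  expect_error(fit_ancova(tab, analysis_spec("y", covariates = c("sex", "t2d", "dup"))),
               "aliased")
})

test_that("Rubin pooling reproduces the hand-computed fixture and identities", {
  pc <- pool_rubin(c(1, 3), c(1, 1))
  expect_equal(pc$qbar, 2)
  expect_equal(pc$W, 1)
  expect_equal(pc$B, 2)
  expect_equal(pc$T, 4)
  expect_equal(pc$se, 2)
  # identical estimates collapse the between variance
  pc0 <- pool_rubin(c(1.5, 1.5, 1.5), c(0.2, 0.2, 0.2))
  expect_equal(pc0$B, 0)
  expect_equal(pc0$T, pc0$W)
  # homogeneity: scaling estimates by c scales qbar by c and T by c^2
  set.seed(4)
  est <- rnorm(5); v <- runif(5, 0.5, 2)
  p1 <- pool_rubin(est, v); p2 <- pool_rubin(3 * est, 9 * v)
  expect_equal(p2$qbar, 3 * p1$qbar)
  expect_equal(p2$T, 9 * p1$T)
  # T = W + (1 + 1/m) B to machine precision on random inputs
  for (i in 1:20) {
    m <- sample(2:10, 1)
    p <- pool_rubin(rnorm(m), runif(m, 0.1, 2), dfcom = 100)
    expect_equal(p$T, p$W + (1 + 1 / m) * p$B, tolerance = 1e-14)
    expect_true(p$ci_low <= p$qbar && p$qbar <= p$ci_high)
    expect_gte(p$T, p$W)
  }
  expect_error(pool_rubin(1, 1), "m >= 2")
})

test_that("identical completions collapse the pooled omnibus to the F test", {
  set.seed(5)
  tab <- gaussian_trial(40, effects = c(0.5, -1, 0))
  gl <- pooled_global_test(rep(list(tab), 5), spec_y)
  # independent oracle: extra-sum-of-squares F for the arm factor
  d <- data.frame(change = tab$y_m12 - tab$y_m0, arm = tab$arm,
                  y_m0 = tab$y_m0, sex = tab$sex, t2d = tab$t2d)
  f0 <- lm(change ~ y_m0 + sex + t2d, d)
  f1 <- lm(change ~ arm + y_m0 + sex + t2d, d)
  Fref <- anova(f0, f1)$F[2]
  expect_equal(gl$statistic, Fref, tolerance = 1e-8)
  expect_error(pooled_global_test(list(tab[tab$arm != "UC", ]), spec_y),
               "3 arms")
})

test_that("the pooled omnibus test is calibrated under the global null", {
  # proper normal-model imputation (independent of the PMM engine) isolates
  # the pooling rule; nominal 0.05 within a 3-SE binomial band at 1,000 reps
  set.seed(6)
  rej <- vapply(1:1000, function(i) {
    tab <- blank_y(gaussian_trial(50))
    stk <- norm_impute_y(tab, 5)
    pooled_global_test(stk, spec_y)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.035)
  expect_lt(mean(rej), 0.065)
})

test_that("the pooled omnibus test has power against a planted 2-SD effect", {
  set.seed(7)
  rej <- vapply(1:200, function(i) {
    tab <- blank_y(gaussian_trial(50, effects = c(0, -6, 0)))  # 2 x SD 3
    stk <- norm_impute_y(tab, 5)
    pooled_global_test(stk, spec_y)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.9)
})

test_that("gatekeeping releases pairwise contrasts only on a significant omnibus", {
  set.seed(8)
  null_tab <- gaussian_trial(40)
  gl <- pooled_global_test(rep(list(null_tab), 3), spec_y)
  gl$p <- 0.40; gl$significant <- FALSE
  gk <- gatekeep_pairwise(gl, rep(list(null_tab), 3), spec_y)
  expect_equal(gk$status, "gatekept")
  expect_equal(nrow(gk$contrasts), 0)

  eff_tab <- gaussian_trial(50, effects = c(-1.46, -1.76, 0))
  stk <- rep(list(eff_tab), 3)
  gl2 <- pooled_global_test(stk, spec_y)
  gk2 <- gatekeep_pairwise(gl2, stk, spec_y)
  expect_equal(gk2$status, "released")
  expect_setequal(gk2$contrasts$label,
                  c("LCPUFA vs HND", "LCPUFA vs UC", "HND vs UC"))
  expect_equal(nrow(gk2$contrasts), 3)
})

test_that("gatekeeping keeps the familywise error at or below the omnibus rate", {
  set.seed(9)
  res <- t(vapply(1:500, function(i) {
    tab <- gaussian_trial(50)
    stk <- rep(list(tab), 2)
    gl <- pooled_global_test(stk, spec_y)
    gk <- gatekeep_pairwise(gl, stk, spec_y)
    any_pair <- gk$status == "released" && any(gk$contrasts$p < 0.05)
    c(omnibus = gl$significant, pairwise = any_pair)
  }, c(omnibus = TRUE, pairwise = TRUE)))
  expect_lte(mean(res[, "pairwise"]), mean(res[, "omnibus"]))
  # familywise rate below nominal + 3 binomial SEs
  expect_lte(mean(res[, "pairwise"]),
             0.05 + 3 * sqrt(0.05 * 0.95 / 500))
})

test_that("Shapiro-Wilk routing separates Gaussian from lognormal residuals", {
  set.seed(10)
  gauss_ok <- vapply(1:200, function(i) {
    tab <- gaussian_trial(50)
    residual_normality(list(tab), spec_y)$gaussian
  }, TRUE)
  expect_gte(mean(gauss_ok), 0.95)
  skew_flagged <- vapply(1:200, function(i) {
    tab <- gaussian_trial(50, resid_sd = 0)
    tab$y_m12 <- tab$y_m12 + rlnorm(nrow(tab), 0, 1)
    !residual_normality(list(tab), spec_y)$gaussian
  }, TRUE)
  expect_gte(mean(skew_flagged), 0.95)
  # the rule is strict: W equal to the threshold is not Gaussian
  tab <- gaussian_trial(50)
  nc <- residual_normality(list(tab), spec_y)
  expect_false(residual_normality(list(tab), spec_y,
                                  threshold = nc$summary_W)$gaussian)
})
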