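# Shared fixtures built in code.

# Minimal Gaussian three-arm table with a generic outcome "y": baseline
# correlated with change, arm effects additive on the change scale.
gaussian_trial <- function(n_per_arm = 50, effects = c(0, 0, 0),
                           resid_sd = 3, baseline_slope = 0.3) {
  n <- 3 * n_per_arm
  arm <- rep(c("LCPUFA", "HND", "UC"), each = n_per_arm)
  base <- rnorm(n, 8, 3)
  change <- effects[match(arm, c("LCPUFA", "HND", "UC"))] +
    baseline_slope * (base - 8) + rnorm(n, 0, resid_sd)
  data.frame(id = seq_len(n), arm = arm,
             sex = sample(c("man", "woman"), n, TRUE),
             t2d = runif(n) < 0.5, y_m0 = base, y_m12 = base + change)
}

# Blank y_m12 at the given marginal rate, MAR on the baseline.
blank_y <- function(tab, rate = 0.14, slope = 0.15) {
  p <- trialmi:::mar_probs(slope * (tab$y_m0 - mean(tab$y_m0)), rate)
  tab$y_m12[runif(nrow(tab)) < p] <- NA
  tab
}

# Proper normal-model multiple imputation of y_m12 — an independent
# imputation oracle for testing the pooling machinery separately from the
# package's PMM engine.
norm_impute_y <- function(tab, m) {
  ry <- !is.na(tab$y_m12)
  X <- model.matrix(~ arm + y_m0 + sex + t2d, tab)
  fit <- lm.fit(X[ry, ], tab$y_m12[ry])
  R <- qr.R(qr(X[ry, ]))
  df <- sum(ry) - ncol(X)
  lapply(seq_len(m), function(j) {
    s2 <- sum(fit$residuals^2) / rchisq(1, df)
    bs <- fit$coefficients + sqrt(s2) * backsolve(R, rnorm(ncol(X)))
    t2 <- tab
    t2$y_m12[!ry] <- drop(X[!ry, , drop = FALSE] %*% bs) +
      rnorm(sum(!ry), 0, sqrt(s2))
    t2
  })
}

spec_y <- trialmi::analysis_spec("y")
ALL_PAIRS <- list(c("LCPUFA", "HND"), c("LCPUFA", "UC"), c("HND", "UC"))
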