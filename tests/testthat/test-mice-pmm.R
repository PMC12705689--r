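test_that("a complete table yields m identical completions", {
  set.seed(1)
  tab <- gaussian_trial(20)
  stk <- impute_mice_pmm(tab, imputation_model(predictors = c("arm", "sex", "t2d"), m = 4, seed = 2),
                         variables = "y_m12")
  expect_length(stk$completions, 4)
  for (j in 1:4) expect_identical(stk$completions[[j]], tab)
})

test_that("imputed cells are observed donor values; observed cells untouched", {
  set.seed(3)
  tab <- blank_y(gaussian_trial(50))
  obs <- tab$y_m12[!is.na(tab$y_m12)]
  stk <- impute_mice_pmm(tab, imputation_model(predictors = c("arm", "sex", "t2d"), m = 5, seed = 4),
                         variables = "y_m12")
  nas <- is.na(tab$y_m12)
  for (j in 1:5) {
    done <- stk$completions[[j]]
    expect_identical(done$y_m12[!nas], tab$y_m12[!nas])   # bitwise equal
    expect_true(all(done$y_m12[nas] %in% obs))            # PMM donor property
    expect_false(anyNA(done$y_m12))
  }
  # between-imputation variance of imputed cells is positive with k > 1
  imp <- sapply(stk$completions, function(d) d$y_m12[nas])
  expect_gt(mean(apply(imp, 1, var)), 0)
})

test_that("k = 1 improper matching reproduces the nearest-neighbor oracle", {
  # toy table, one missing cell; oracle = OLS predictions by normal
  # equations, donor with nearest prediction
  set.seed(6)
  for (rep in 1:10) {
    n <- 9
    tab <- data.frame(id = 1:n, arm = rep(c("LCPUFA", "HND", "UC"), 3),
                      sex = rep(c("man", "woman"), length.out = n),
                      t2d = rep(c(TRUE, FALSE), length.out = n),
                      y_m0 = rnorm(n, 8, 2))
    tab$y_m12 <- tab$y_m0 + rnorm(n)
    tab$y_m12[4] <- NA
    mod <- imputation_model(predictors = c("y_m0"), m = 2,
                            k_donors = 1, proper = FALSE, seed = rep)
    stk <- impute_mice_pmm(tab, mod, variables = "y_m12")
    # brute-force oracle on the same predictor set (intercept + y_m0)
    ry <- !is.na(tab$y_m12)
    X <- cbind(1, tab$y_m0)
    beta <- solve(t(X[ry, ]) %*% X[ry, ], t(X[ry, ]) %*% tab$y_m12[ry])
    pred <- drop(X %*% beta)
    donor <- which(ry)[which.min(abs(pred[ry] - pred[4]))]
    for (j in 1:2)
      expect_identical(stk$completions[[j]]$y_m12[4], tab$y_m12[donor])
  }
})

test_that("degenerate inputs fail loudly and collinear terms are dropped", {
  tab <- gaussian_trial(10)
  tab$y_m12 <- NA_real_
  expect_error(impute_mice_pmm(tab, imputation_model(predictors = c("arm", "sex", "t2d"), m = 2),
                               variables = "y_m12"), "unimputable")
  set.seed(8)
  tab2 <- blank_y(gaussian_trial(30))
  tab2$dup <- tab2$y_m0   # exact copy -> aliased in the conditional model
  mod <- imputation_model(predictors = c("arm", "sex", "t2d", "dup"),
                          m = 2, seed = 9)
  stk <- impute_mice_pmm(tab2, mod, variables = "y_m12")
  expect_false(anyNA(stk$completions[[1]]$y_m12))
  expect_gt(length(stk$log$y_m12$dropped), 0)
})

test_that("imputation is deterministic under a fixed seed", {
  set.seed(10)
  tab <- blank_y(gaussian_trial(40))
  s1 <- impute_mice_pmm(tab, imputation_model(predictors = c("arm", "sex", "t2d"), m = 3, seed = 42), "y_m12")
  s2 <- impute_mice_pmm(tab, imputation_model(predictors = c("arm", "sex", "t2d"), m = 3, seed = 42), "y_m12")
  expect_identical(s1$completions, s2$completions)
})

test_that("MI corrects the complete-case bias of a selective MAR mechanism", {
  # Mechanism: missingness of the outcome depends (steeply) on observed
  # weight change, which also carries half the arm effect. Complete-case
  # ANCOVA, which omits weight change, is biased; PMM imputation with
  # weight change in the model recovers the planted -1.5 contrast.
  mk <- function(n_per_arm = 1000) {
    n <- 2 * n_per_arm
    arm <- rep(c("HND", "UC"), each = n_per_arm)
    base <- rnorm(n, 8, 3)
    wc <- rnorm(n, ifelse(arm == "HND", -2.77, 0), 4)
    change <- -0.115 * (arm == "HND") + 0.5 * wc + 0.3 * (base - 8) +
      rnorm(n, 0, 2)
    data.frame(id = 1:n, arm = arm,
               sex = sample(c("man", "woman"), n, TRUE),
               t2d = runif(n) < 0.5, y_m0 = base, y_m12 = base + change,
               weight_change = wc)
  }
  set.seed(31)
  out <- t(sapply(1:200, function(i) {
    tab <- mk()
    p <- trialmi:::mar_probs(1.2 * tab$weight_change, 0.14)
    tab$y_m12[runif(nrow(tab)) < p] <- NA
    cc <- tab[!is.na(tab$y_m12), ]
    ctc <- fit_ancova(cc, spec_y)$contrasts
    mod <- imputation_model(m = 5,
                            predictors = c("arm", "sex", "t2d",
                                           "weight_change"), seed = NULL)
    stk <- impute_mice_pmm(tab, mod, variables = "y_m12")
    mi <- pool_ancova_contrasts(stk, spec_y, pairs = list(c("HND", "UC")))
    c(cc = ctc$estimate[ctc$label == "HND vs UC"], mi = mi$estimate)
  }))
  truth <- -1.5
  expect_gt(abs(mean(out[, "cc"]) - truth), 0.3)      # complete-case bias
  expect_lt(abs(mean(out[, "mi"]) - truth), 0.15)     # MI recovery
})

test_that("imputed stacks serialize to CSVs plus provenance", {
  set.seed(12)
  tab <- blank_y(gaussian_trial(15))
  stk <- impute_mice_pmm(tab, imputation_model(predictors = c("arm", "sex", "t2d"), m = 2, seed = 1), "y_m12")
  dir <- file.path(tempdir(), "stack_out")
  write_imputed_stack(stk, dir)
  expect_true(file.exists(file.path(dir, "completion_01.csv")))
  prov <- jsonlite::read_json(file.path(dir, "provenance.json"))
  expect_equal(prov$m, 2)
  expect_equal(prov$k_donors, 5)
  unlink(dir, recursive = TRUE)
})
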