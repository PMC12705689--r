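test_that("trial CSVs round-trip including missing cells", {
  tab <- generate_trial(seed = 3)
  path <- tempfile(fileext = ".csv")
  write_trial_csv(tab, path)
  back <- read_trial_csv(path)
  expect_equal(back, tab, tolerance = 1e-12)
  expect_true(anyNA(back$liver_fat_m12))
  # empty fields are missing, never zero
  expect_identical(which(is.na(back$liver_fat_m12)),
                   which(is.na(tab$liver_fat_m12)))
  unlink(path)
})

test_that("malformed trial CSVs are rejected with location information", {
  tab <- generate_trial(generator_config(n_per_arm = 5), seed = 4)
  tab$arm[3] <- "HDN"
  p1 <- tempfile(fileext = ".csv"); write.csv(tab, p1, row.names = FALSE)
  expect_error(read_trial_csv(p1), "HDN.*row 3")
  tab2 <- generate_trial(generator_config(n_per_arm = 5), seed = 4)
  tab2$liver_fat_m12 <- as.character(tab2$liver_fat_m12)
  tab2$liver_fat_m12[2] <- "oops"
  p2 <- tempfile(fileext = ".csv"); write.csv(tab2, p2, row.names = FALSE, na = "")
  expect_error(read_trial_csv(p2), "non-numeric.*liver_fat_m12")
  unlink(c(p1, p2))
})

test_that("the ITT pipeline recovers planted effects and reports its route", {
  set.seed(5)
  tab <- blank_y(gaussian_trial(80, effects = c(-2, -3, 0)), rate = 0.10)
  cfg <- run_config(outcomes = "y", m = 5, B = 150, seed = 7)
  rep <- run_primary_analysis(tab, cfg)
  r <- rep$outcomes$y
  expect_equal(r$branch, "parametric")
  expect_equal(r$population, "ITT")
  expect_equal(r$n_analyzed, nrow(tab))
  expect_equal(r$status, "released")
  ct <- r$contrasts
  # planted values inside the pooled CIs
  lo <- setNames(ct$ci_low, ct$label); hi <- setNames(ct$ci_high, ct$label)
  expect_true(lo["HND vs UC"] <= -3 && -3 <= hi["HND vs UC"])
  expect_true(lo["LCPUFA vs UC"] <= -2 && -2 <= hi["LCPUFA vs UC"])
  # determinism: same table, same config -> byte-identical report
  rep2 <- run_primary_analysis(tab, cfg)
  expect_identical(rep, rep2)
})

test_that("a global-null trial is gatekept with no pairwise contrasts", {
  set.seed(11)
  tab <- blank_y(gaussian_trial(50), rate = 0.10)
  cfg <- run_config(outcomes = "y", m = 5, B = 150, seed = 3)
  rep <- run_primary_analysis(tab, cfg)
  r <- rep$outcomes$y
  expect_equal(r$status, "gatekept")
  expect_equal(nrow(r$contrasts), 0)
})

test_that("skewed residuals route to the nonparametric branch", {
  set.seed(6)
  tab <- gaussian_trial(50, effects = c(0, -2, 0), resid_sd = 0)
  tab$y_m12 <- tab$y_m12 + rlnorm(nrow(tab), 0, 1.2)
  cfg <- run_config(outcomes = "y", m = 5, B = 150, seed = 9)
  rep <- run_primary_analysis(tab, cfg)
  r <- rep$outcomes$y
  expect_equal(r$branch, "nonparametric")
  expect_false(r$normality$gaussian)
  if (r$status == "released")
    expect_s3_class(r$contrasts, "median_contrasts")
})

test_that("the per-protocol population analyzes complete cases only", {
  set.seed(7)
  tab <- blank_y(gaussian_trial(50, effects = c(-2, -3, 0)), rate = 0.15)
  cfg <- run_config(outcomes = "y", population = "per_protocol",
                    m = 5, seed = 2)
  rep <- run_primary_analysis(tab, cfg)
  r <- rep$outcomes$y
  expect_equal(r$population, "per_protocol")
  expect_equal(r$n_analyzed, sum(!is.na(tab$y_m12)))
  expect_lt(r$n_analyzed, nrow(tab))
})

test_that("subgroup runs drop the stratifier from the covariates", {
  set.seed(8)
  tab <- blank_y(gaussian_trial(60, effects = c(-2, -3, 0)), rate = 0.08)
  cfg <- run_config(outcomes = "y", m = 3, B = 150,
                    subgroups = "sex", seed = 4)
  reps <- run_subgroups(tab, cfg)
  expect_setequal(names(reps$sex), c("man", "woman"))
  expect_equal(reps$sex$man$covariates, "t2d")
  # undersized levels are skipped with a warning
  tab$grp <- c(rep("tiny", 5), rep("big", nrow(tab) - 5))
  cfg2 <- run_config(outcomes = "y", m = 3, subgroups = "grp", seed = 4)
  expect_warning(run_subgroups(tab, cfg2), "too small")
  # absent subgroup columns warn rather than fail
  cfg3 <- run_config(outcomes = "y", m = 3, subgroups = "pnpla3", seed = 4)
  expect_warning(run_subgroups(tab, cfg3), "absent")
})

test_that("sensitivity variants equal the primary when they change nothing", {
  set.seed(9)
  tab <- blank_y(gaussian_trial(40, effects = c(-2, -3, 0)), rate = 0.08)
  cfg <- run_config(outcomes = "y", m = 4, B = 150, seed = 6)
  sens <- run_sensitivity(tab, cfg)
  # no household pairs present: excluding them is a no-op
  expect_identical(sens$primary$outcomes$y$contrasts,
                   sens$exclude_pairs$outcomes$y$contrasts)
  # the BMI-visit variant records its augmented predictor set
  tabb <- tab
  tabb$bmi_m0 <- rnorm(nrow(tab), 30, 3)
  tabb$bmi_m6 <- tabb$bmi_m0 + rnorm(nrow(tab), 0, 0.5)
  tabb$bmi_m12 <- tabb$bmi_m0 + rnorm(nrow(tab), 0, 1)
  sens2 <- run_sensitivity(tabb, cfg)
  expect_true(all(c("bmi_m6", "bmi_m12") %in%
                    sens2$bmi_visits$outcomes$y$imputation$predictors))
  expect_false(any(c("bmi_m6", "bmi_m12") %in%
                     sens2$primary$outcomes$y$imputation$predictors))
  # deltas are reported per contrast
  d <- sens2$deltas$bmi_visits$y
  if (!is.null(d)) expect_true(all(c("label", "delta") %in% names(d)))
})

test_that("reports serialize to JSON with config hash and seed", {
  set.seed(10)
  tab <- blank_y(gaussian_trial(40, effects = c(-2, -3, 0)), rate = 0.08)
  cfg <- run_config(outcomes = "y", m = 3, B = 150, seed = 8)
  rep <- run_primary_analysis(tab, cfg)
  expect_match(rep$config_hash, "^[0-9a-f]{32}$")
  path <- tempfile(fileext = ".json")
  write_report(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$seed, 8)
  expect_equal(back$config_hash, rep$config_hash)
  unlink(c(path, paste0(path, ".csv")))
})

test_that("household exclusion changes estimates only modestly in simulation", {
  set.seed(12)
  cfg_gen <- generator_config(n_per_arm = 50, n_household_pairs = 4)
  deltas <- vapply(1:20, function(i) {
    tab <- generate_cohort(cfg_gen, seed = 500 + i)
    sp <- analysis_spec("liver_fat")
    full <- fit_ancova(tab, sp)$contrasts
    drop8 <- fit_ancova(tab[is.na(tab$household_id), ], sp)$contrasts
    max(abs(full$estimate - drop8$estimate))
  }, 0)
  # dropping 8 of 150 moves planted-effect estimates by < 0.5 outcome SDs
  expect_lt(mean(deltas), 0.5 * 3)
  expect_true(all(deltas < 1.5 * 3))
})
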