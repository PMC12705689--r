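## harness: orchestration of the full analysis — imputation, residual
## routing between the parametric and nonparametric branches, gatekept
## contrasts, subgroup and sensitivity runs, and operating-characteristic
## simulations.

#' Run configuration
#'
#' @param outcomes outcome column stems to analyze.
#' @param population `"ITT"` (multiply imputed, all subjects) or
#'   `"per_protocol"` (complete cases).
#' @param branch `"auto"` (Shapiro-Wilk routing), `"parametric"` or
#'   `"nonparametric"`.
#' @param m imputations for the primary pipeline (trial value 20).
#' @param B bootstrap resamples for the nonparametric CI (trial value
#'   10,000; desk preset 500).
#' @param m_per_bootstrap imputations inside each bootstrap resample.
#' @param alpha two-sided significance level used everywhere.
#' @param subgroups stratifying variables for [run_subgroups()].
#' @param exclude_household_pairs,bmi_visits_in_imputation sensitivity
#'   switches for [run_sensitivity()].
#' @param seed run seed.
#' @return list of class `run_config`.
#' @export
run_config <- function(outcomes = "liver_fat",
                       population = c("ITT", "per_protocol"),
                       branch = c("auto", "parametric", "nonparametric"),
                       m = 20, B = 500, m_per_bootstrap = 2, alpha = 0.05,
                       subgroups = c("sex", "t2d", "pnpla3", "nafld_m0"),
                       exclude_household_pairs = FALSE,
                       bmi_visits_in_imputation = FALSE, seed = 1) {
  population <- match.arg(population)
  branch <- match.arg(branch)
  structure(list(outcomes = outcomes, population = population,
                 branch = branch, m = m, B = B,
                 m_per_bootstrap = m_per_bootstrap, alpha = alpha,
                 subgroups = subgroups,
                 exclude_household_pairs = exclude_household_pairs,
                 bmi_visits_in_imputation = bmi_visits_in_imputation,
                 seed = seed),
            class = "run_config")
}

## columns the analysis of one outcome touches
outcome_columns <- function(table, outcome, covariates) {
  cols <- c(paste0(outcome, "_m0"), paste0(outcome, "_m12"), covariates)
  intersect(cols, names(table))
}

## imputation predictor set for a run (sensitivity variant B adds the
## month-6/month-12 BMI visits)
imputation_predictors <- function(table, config, covariates) {
  base <- intersect(c("arm", "bmi_m0", "age", covariates), names(table))
  if (isTRUE(config$bmi_visits_in_imputation))
    base <- union(base, intersect(c("bmi_m6", "bmi_m12"), names(table)))
  base
}

## analyze one outcome on one table under one config
analyze_outcome <- function(table, outcome, config, covariates = c("sex", "t2d"),
                            seed_offset = 0) {
  spec <- analysis_spec(outcome, covariates = covariates,
                        alpha = config$alpha)
  seed <- child_seed(config$seed, seed_offset)
  cols <- outcome_columns(table, outcome, covariates)
  report <- list(outcome = outcome, population = config$population,
                 alpha = config$alpha)

  if (config$population == "per_protocol") {
    cc <- table[complete.cases(table[cols]), , drop = FALSE]
    report$n_analyzed <- nrow(cc)
    nc <- residual_normality(list(cc), spec)
    report$normality <- list(summary_W = nc$summary_W,
                             gaussian = nc$gaussian)
    branch <- route_branch(config$branch, nc$gaussian)
    report$branch <- branch
    if (branch == "parametric") {
      gl <- pooled_global_test(list(cc), spec)
      gl$significant <- gl$p < config$alpha
      gk <- gatekeep_pairwise(gl, list(cc, cc), spec)
      report$global <- gl[c("statistic", "df1", "df2", "p", "significant")]
      report$status <- gk$status
      report$contrasts <- gk$contrasts
    } else {
      adj <- adjusted_residuals(cc, spec)
      kw <- kruskal_wallis(adj, cc$arm)
      report$global <- kw
      if (kw$p < config$alpha) {
        report$status <- "released"
        report$contrasts <- do.call(rbind, lapply(ARM_PAIRS, function(p) {
          if (!all(p %in% cc$arm)) return(NULL)
          hl <- hodges_lehmann(adj[cc$arm == p[1]], adj[cc$arm == p[2]])
          data.frame(label = pair_label(p), estimate = hl$estimate,
                     ci_low = hl$ci_low, ci_high = hl$ci_high,
                     p = NA_real_)
        }))
      } else {
        report$status <- "gatekept"
        report$contrasts <- data.frame()
      }
    }
    return(report)
  }

  ## ITT: impute, route, test, contrast
  report$n_analyzed <- nrow(table)
  to_impute <- cols[vapply(cols, function(v) anyNA(table[[v]]), TRUE)]
  preds <- imputation_predictors(table, config, covariates)
  model <- imputation_model(predictors = preds, m = config$m,
                            seed = child_seed(seed, 1))
  stack <- if (length(to_impute))
    impute_mice_pmm(table, model, variables = to_impute)
  else structure(list(completions = rep(list(table), config$m),
                      m = config$m, model = model, variables = character(),
                      seed = model$seed, log = list()),
                 class = "imputed_stack")
  report$imputation <- list(m = config$m, variables = to_impute,
                            predictors = preds)
  nc <- residual_normality(stack, spec)
  report$normality <- list(summary_W = nc$summary_W, gaussian = nc$gaussian)
  branch <- route_branch(config$branch, nc$gaussian)
  report$branch <- branch
  if (branch == "parametric") {
    gl <- pooled_global_test(stack, spec)
    gk <- gatekeep_pairwise(gl, stack, spec)
    report$global <- gl[c("statistic", "df1", "df2", "p", "significant")]
    report$status <- gk$status
    report$contrasts <- gk$contrasts
  } else {
    kw <- mi_kw_test(stack, spec)
    report$global <- list(p = kw$p, rule = kw$rule)
    if (kw$p < config$alpha) {
      report$status <- "released"
      report$contrasts <- boot_impute_median_contrasts(
        table, spec, B = config$B,
        m_per_bootstrap = config$m_per_bootstrap,
        seed = child_seed(seed, 2))
    } else {
      report$status <- "gatekept"
      report$contrasts <- data.frame()
    }
  }
  report
}

route_branch <- function(requested, gaussian) {
  switch(requested,
         auto = if (gaussian) "parametric" else "nonparametric",
         parametric = "parametric",
         nonparametric = "nonparametric")
}

#' Run the primary analysis pipeline
#'
#' For each configured outcome: in the intention-to-treat population,
#' impute `m` times by chained-equation PMM, check residual normality of
#' the baseline-adjusted ANCOVA (Shapiro-Wilk median W, strict 0.95 rule),
#' then either pool the omnibus Wald test and release gatekept pairwise
#' Rubin contrasts (Gaussian route) or run the residual-method
#' Kruskal-Wallis gate followed by bootstrap-then-impute adjusted median
#' contrasts (non-Gaussian route). The per-protocol population uses
#' complete cases, with Hodges-Lehmann contrasts on the non-Gaussian
#' route. The report records which branch fired and why, the run seed and
#' a configuration hash; equal config hash and seed reproduce the report
#' exactly.
#'
#' @param table a trial table (see [generate_trial()], [read_trial_csv()]).
#' @param config a [run_config()].
#' @return list of class `trial_report`: `config_hash`, `seed`,
#'   `population`, `outcomes` (named list of per-outcome reports).
#' @export
run_primary_analysis <- function(table, config = run_config()) {
  validate_trial(table)
  missing_arms <- setdiff(ARM_LEVELS, unique(as.character(table$arm)))
  if (length(missing_arms))
    stop_config("arm(s) absent from table: %s",
                paste(missing_arms, collapse = ", "))
  outs <- setNames(vector("list", length(config$outcomes)), config$outcomes)
  for (i in seq_along(config$outcomes))
    outs[[i]] <- analyze_outcome(table, config$outcomes[i], config,
                                 seed_offset = i)
  structure(list(config_hash = config_hash(unclass(config)),
                 seed = config$seed, population = config$population,
                 version = as.character(utils::packageVersion("trialmi")),
                 outcomes = outs),
            class = "trial_report")
}

#' @export
print.trial_report <- function(x, ...) {
  cat(sprintf("trial report (%s population, seed %s, config %s)\n",
              x$population, x$seed, substr(x$config_hash, 1, 8)))
  for (oc in names(x$outcomes)) {
    r <- x$outcomes[[oc]]
    cat(sprintf("- %s [%s branch, %s]\n", oc, r$branch, r$status))
    if (is.data.frame(r$contrasts) && nrow(r$contrasts))
      for (i in seq_len(nrow(r$contrasts)))
        cat(sprintf("    %s: %.3f (%.3f, %.3f)\n",
                    r$contrasts$label[i], r$contrasts$estimate[i],
                    r$contrasts$ci_low[i], r$contrasts$ci_high[i]))
  }
  invisible(x)
}

#' Subgroup analyses
#'
#' Re-runs the primary pipeline within each level of each subgroup
#' variable, with the stratifying variable dropped from the covariate set
#' when it is one. Imputation happens separately per subgroup. When
#' stratifying by baseline steatosis status and that status has missing
#' values, the status is imputed first (PMM on its 0/1 coding) and the
#' first completion's status defines the strata. Levels with fewer than
#' `3 * arms` subjects are skipped with a warning.
#'
#' @param table trial table; `config` a [run_config()].
#' @return nested list: subgroup variable -> level -> `trial_report`.
#' @export
run_subgroups <- function(table, config = run_config()) {
  reports <- list()
  for (sv in config$subgroups) {
    if (!sv %in% names(table)) {
      warning(sprintf("subgroup variable '%s' absent; skipped", sv))
      next
    }
    tab <- table
    if (anyNA(tab[[sv]])) {
      ## impute the stratifier first, then stratify
      mod <- imputation_model(
        predictors = intersect(c("arm", "bmi_m0", "age", "sex", "t2d"),
                               setdiff(names(tab), sv)),
        m = 2, seed = child_seed(config$seed, 97))
      stk <- impute_mice_pmm(tab, mod, variables = sv)
      tab[[sv]] <- stk$completions[[1]][[sv]]
    }
    covars <- setdiff(c("sex", "t2d"), sv)
    lev_reports <- list()
    for (lv in sort(unique(as.character(tab[[sv]])))) {
      sub <- tab[as.character(tab[[sv]]) == lv, , drop = FALSE]
      n_arms <- length(unique(sub$arm))
      if (nrow(sub) < 3 * n_arms || n_arms < 3) {
        warning(sprintf("subgroup %s = %s too small (n = %d); skipped",
                        sv, lv, nrow(sub)))
        next
      }
      outs <- setNames(vector("list", length(config$outcomes)),
                       config$outcomes)
      for (i in seq_along(config$outcomes))
        outs[[i]] <- analyze_outcome(sub, config$outcomes[i], config,
                                     covariates = covars, seed_offset = i)
      lev_reports[[lv]] <- list(covariates = covars, n = nrow(sub),
                                outcomes = outs)
    }
    reports[[sv]] <- lev_reports
  }
  reports
}

#' Sensitivity analyses
#'
#' Variant A re-runs the primary analysis after excluding all members of
#' co-randomized household pairs; variant B re-runs it with month-6 and
#' month-12 BMI added to the imputation predictor set. Both report the
#' change in each pairwise estimate relative to the primary run.
#'
#' @param table trial table; `config` a [run_config()].
#' @return list with `primary`, `exclude_pairs`, `bmi_visits`, and
#'   `deltas` (per variant, per outcome, estimate differences).
#' @export
run_sensitivity <- function(table, config = run_config()) {
  primary <- run_primary_analysis(table, config)
  out <- list(primary = primary)

  has_pairs <- "household_id" %in% names(table) &&
    any(!is.na(table$household_id))
  tab_a <- if (has_pairs)
    table[is.na(table$household_id), , drop = FALSE] else table
  out$exclude_pairs <- run_primary_analysis(tab_a, config)

  cfg_b <- config
  cfg_b$bmi_visits_in_imputation <- TRUE
  out$bmi_visits <- run_primary_analysis(table, cfg_b)

  delta_of <- function(variant) {
    lapply(setNames(nm = config$outcomes), function(oc) {
      p <- primary$outcomes[[oc]]$contrasts
      v <- variant$outcomes[[oc]]$contrasts
      if (!is.data.frame(p) || !is.data.frame(v) || !nrow(p) || !nrow(v))
        return(NULL)
      mg <- merge(p[c("label", "estimate")], v[c("label", "estimate")],
                  by = "label", suffixes = c("_primary", "_variant"))
      mg$delta <- mg$estimate_variant - mg$estimate_primary
      mg
    })
  }
  out$deltas <- list(exclude_pairs = delta_of(out$exclude_pairs),
                     bmi_visits = delta_of(out$bmi_visits))
  out
}

## lightweight null three-arm trial for operating-characteristic runs:
## Gaussian change scores, zero arm effects, baseline correlated with
## change, sex/T2D covariates
sim_null_trial <- function(n_per_arm, effect = c(0, 0, 0)) {
  n <- 3 * n_per_arm
  arm <- rep(ARM_LEVELS, each = n_per_arm)
  baseline <- rnorm(n, 8, 3)
  change <- effect[match(arm, ARM_LEVELS)] + 0.3 * (baseline - 8) +
    rnorm(n, 0, 3)
  data.frame(id = seq_len(n), arm = arm,
             sex = sample(c("man", "woman"), n, TRUE),
             t2d = runif(n) < 0.5,
             y_m0 = baseline, y_m12 = baseline + change)
}

## single-dataset gatekept ANCOVA: omnibus F, then pairwise refits
gatekept_single <- function(tab, spec) {
  ft <- fit_ancova(tab, spec)
  k <- length(ft$arm_coefs)
  stat <- drop(t(ft$arm_coefs) %*% solve(ft$arm_vcov) %*% ft$arm_coefs) / k
  p_global <- pf(stat, k, ft$dfcom, lower.tail = FALSE)
  if (p_global >= spec$alpha) return(FALSE)
  for (pr in ARM_PAIRS) {
    sub <- tab[tab$arm %in% pr, , drop = FALSE]
    f2 <- fit_ancova(sub, spec)
    ct <- f2$contrasts[1, ]
    tstat <- ct$estimate / sqrt(ct$variance)
    if (2 * pt(abs(tstat), f2$dfcom, lower.tail = FALSE) < spec$alpha)
      return(TRUE)
  }
  FALSE
}

#' Operating-characteristic simulations
#'
#' Validates the pipeline's statistical properties by direct simulation:
#' \describe{
#'   \item{`"null_fwer"`}{familywise any-pairwise rejection rate of the
#'     gatekept three-arm ANCOVA under a global null (Gaussian change
#'     scores, baseline covariate correlated with change, n = 50/arm).}
#'   \item{`"power"`}{two-sample t-test rejection rate at the design point
#'     (difference 2, SD 3, n = 37/group).}
#'   \item{`"coverage"`}{bootstrap-then-impute 95% CI coverage of a zero
#'     adjusted median difference under symmetric noise with missing
#'     outcome data.}
#'   \item{`"mediation_pm"`}{mean recovered proportion mediated when the
#'     planted PM is 50%.}
#' }
#'
#' @param scenario one of the above.
#' @param reps replicates (>= 500 for rates, >= 200 for coverage).
#' @param seed RNG seed.
#' @param n_per_arm per-arm size for trial-level scenarios.
#' @param B,m_per_bootstrap bootstrap settings for `"coverage"`.
#' @return a `simulation_report` data frame (value, Monte-Carlo SE).
#' @export
simulate_operating_characteristics <- function(
    scenario = c("null_fwer", "power", "coverage", "mediation_pm"),
    reps = 2000, seed = 1, n_per_arm = 50, B = 500, m_per_bootstrap = 2) {
  scenario <- match.arg(scenario)
  spec <- analysis_spec("y")
  if (scenario == "power") {
    if (reps < 500) stop_config("reps must be >= 500 for rates")
    return(empirical_power(design_spec(), 37, reps, seed))
  }
  if (scenario == "null_fwer") {
    if (reps < 500) stop_config("reps must be >= 500 for rates")
    hits <- with_seed(seed, {
      vapply(seq_len(reps), function(i)
        gatekept_single(sim_null_trial(n_per_arm), spec), TRUE)
    })
    return(simulation_report("null_fwer", reps, "rejection_rate",
                             mean(hits), seed))
  }
  if (scenario == "coverage") {
    if (reps < 200) stop_config("reps must be >= 200 for coverage")
    cover <- with_seed(seed, {
      vapply(seq_len(reps), function(i) {
        tab <- sim_null_trial(n_per_arm)
        ## MAR blanking of the outcome at ~14%
        p <- mar_probs(0.15 * (tab$y_m0 - 8), 0.14)
        tab$y_m12[runif(nrow(tab)) < p] <- NA
        ct <- boot_impute_median_contrasts(
          tab, spec, B = B, m_per_bootstrap = m_per_bootstrap,
          seed = NULL, chain_iterations = 3,
          pairs = list(c("HND", "UC")))
        ct$ci_low[1] <= 0 && 0 <= ct$ci_high[1]
      }, TRUE)
    })
    return(simulation_report("boot_impute_coverage", reps, "coverage",
                             mean(cover), seed))
  }
  ## mediation_pm: planted a = -2.77, b = 0.4, c' = a*b so PM = 50%
  if (reps < 200) stop_config("reps must be >= 200")
  a <- -2.77; b <- 0.4; cprime <- a * b
  pms <- with_seed(seed, {
    vapply(seq_len(reps), function(i) {
      n <- 2 * n_per_arm
      armn <- rep(c(1, 0), each = n_per_arm)
      base <- rnorm(n, 8, 3)
      med <- a * armn + rnorm(n, 0, 4.5)
      chg <- cprime * armn + b * med + 0.2 * (base - 8) + rnorm(n, 0, 2)
      tab <- data.frame(id = seq_len(n),
                        arm = ifelse(armn == 1, "HND", "UC"),
                        sex = sample(c("man", "woman"), n, TRUE),
                        t2d = runif(n) < 0.5, y_m0 = base,
                        y_m12 = base + chg, weight_change = med)
      fit_mediation(tab, spec, c("HND", "UC"))$pm_percent
    }, 0)
  })
  simulation_report("mediation_pm_recovery", reps, "bias",
                    mean(pms) - 50, seed)
}
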