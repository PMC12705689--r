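## mice_pmm: multiple imputation by chained equations with predictive mean
## matching. Each incomplete variable is regressed on the current
## completions of the other model variables; missing cells borrow the
## observed value of a donor whose (Bayesian-perturbed) prediction is
## nearest. Imputations are proper by default so Rubin's rules are valid.

#' Imputation model specification
#'
#' The default predictor set mirrors the trial's imputation model: diet
#' group, BMI, age, sex, type 2 diabetes status — plus, implicitly, every
#' modeled variable (baseline value and outcome), since each incomplete
#' variable is regressed on all other variables in the model set.
#'
#' @param predictors always-included predictor columns.
#' @param m number of completed datasets (>= 2; trial value 20).
#' @param chain_iterations chained-equation sweeps per completion.
#' @param k_donors donors eligible per missing cell (>= 1).
#' @param proper draw regression coefficients from their posterior before
#'   matching (required for valid Rubin variance); `FALSE` gives
#'   deterministic OLS-prediction matching, useful for oracle checks.
#' @param seed RNG seed.
#' @return list of class `imputation_model`.
#' @export
imputation_model <- function(predictors = c("arm", "bmi_m0", "age", "sex", "t2d"),
                             m = 20, chain_iterations = 10, k_donors = 5,
                             proper = TRUE, seed = NULL) {
  if (m < 2) stop_config("m must be >= 2")
  if (k_donors < 1) stop_config("k_donors must be >= 1")
  if (chain_iterations < 1) stop_config("chain_iterations must be >= 1")
  structure(list(predictors = predictors, m = m,
                 chain_iterations = chain_iterations, k_donors = k_donors,
                 proper = proper, seed = seed),
            class = "imputation_model")
}

## Impute one variable by PMM given a numeric design matrix.
## y: full vector; ry: observed indicator; X: n x p matrix (no intercept
## column needed; added here). Returns list(values, donors) for the
## missing positions.
pmm_draw <- function(y, ry, X, k, proper) {
  Xo <- cbind(1, X[ry, , drop = FALSE])
  yo <- y[ry]
  fit <- lm.fit(Xo, yo)
  keep <- !is.na(fit$coefficients)
  beta <- fit$coefficients[keep]
  Xo <- Xo[, keep, drop = FALSE]
  Xm <- cbind(1, X[!ry, , drop = FALSE])[, keep, drop = FALSE]
  df <- max(length(yo) - sum(keep), 1)
  if (proper) {
    sigma2 <- sum(fit$residuals^2) / rchisq(1, df)
    R <- qr.R(qr(Xo))
    ## beta* ~ N(beta, sigma2 (X'X)^-1); (X'X)^-1 = R^-1 R^-T
    z <- rnorm(length(beta))
    beta_star <- beta + sqrt(sigma2) * backsolve(R, z)
  } else {
    beta_star <- beta
  }
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(Xm %*% beta_star)
  nmis <- length(yhat_mis)
  donors <- integer(nmis)
  vals <- numeric(nmis)
  obs_idx <- which(ry)
  for (i in seq_len(nmis)) {
    d <- abs(yhat_obs - yhat_mis[i])
    nearest <- order(d)[seq_len(min(k, length(d)))]
    pick <- if (length(nearest) == 1L) nearest else nearest[sample.int(length(nearest), 1L)]
    donors[i] <- obs_idx[pick]
    vals[i] <- yo[pick]
  }
  list(values = vals, donors = donors,
       dropped = names(fit$coefficients)[!keep])
}

#' Multiple imputation by chained equations with predictive mean matching
#'
#' Produces `m` completed copies of the table. Within each completion,
#' incomplete modeled variables are initialized with random draws from
#' their observed values, then updated over `chain_iterations` sweeps: the
#' variable is regressed on all other model-set variables (categoricals
#' indicator-coded), coefficients are posterior-perturbed when
#' `model$proper`, and each missing cell draws uniformly from the
#' `k_donors` observed cases with nearest predictions, taking that donor's
#' observed value. Observed cells are never altered; logical variables are
#' imputed on their 0/1 coding (PMM returns observed 0/1 values).
#'
#' @param table trial table; missingness must be confined to `variables`.
#' @param model an [imputation_model()].
#' @param variables columns to impute; default = all numeric/logical
#'   columns with at least one missing value.
#' @return an object of class `imputed_stack`: list with `completions`
#'   (list of `m` data frames), `m`, `model`, `seed`, and a per-variable
#'   `log` (missing indices, final-iteration donors per completion,
#'   dropped collinear terms).
#' @export
impute_mice_pmm <- function(table, model = imputation_model(),
                            variables = NULL) {
  if (is.null(variables)) {
    cand <- names(table)[vapply(table, function(x)
      (is.numeric(x) || is.logical(x)) && anyNA(x), TRUE)]
    variables <- cand
  }
  for (v in variables) {
    if (!v %in% names(table)) stop_config("unknown variable '%s'", v)
    if (all(is.na(table[[v]])))
      stop_config("variable '%s' has zero observed values; unimputable", v)
  }
  predictors <- setdiff(model$predictors, variables)
  assert_cols(table, predictors)
  for (p in predictors) if (anyNA(table[[p]]))
    stop_config("predictor '%s' has missing values but is not imputed", p)
  incomplete <- variables[vapply(variables, function(v) anyNA(table[[v]]), TRUE)]

  model_set <- union(variables, predictors)
  logicals <- model_set[vapply(table[model_set], is.logical, TRUE)]
  log <- lapply(setNames(incomplete, incomplete), function(v)
    list(missing_rows = which(is.na(table[[v]])), donors = vector("list", model$m),
         dropped = character()))

  completions <- vector("list", model$m)
  for (j in seq_len(model$m)) {
    sj <- child_seed(model$seed, j)
    completions[[j]] <- with_seed(sj, {
      work <- table
      ## initial fill: random observed values
      for (v in incomplete) {
        nas <- is.na(work[[v]])
        obs <- work[[v]][!nas]
        work[[v]][nas] <- sample(obs, sum(nas), replace = TRUE)
      }
      ## with a single incomplete variable the chain has no cross-variable
      ## feedback: one sweep is distributionally identical to many
      iters <- if (length(incomplete) == 1L) 1L else model$chain_iterations
      if (length(incomplete)) {
        for (it in seq_len(iters)) {
          for (v in incomplete) {
            ry <- !is.na(table[[v]])
            others <- setdiff(model_set, v)
            X <- stats::model.matrix(~ . - 1, data = as.data.frame(
              lapply(work[others], function(x)
                if (is.logical(x)) as.numeric(x) else x)))
            res <- pmm_draw(as.numeric(table[[v]]), ry, X,
                            model$k_donors, model$proper)
            filled <- res$values
            if (is.logical(table[[v]])) filled <- as.logical(filled)
            work[[v]][!ry] <- filled
            if (it == iters) {
              ## the block is evaluated in this function's frame, so plain
              ## assignment updates the local log
              log[[v]]$donors[[j]] <- res$donors
              log[[v]]$dropped <- union(log[[v]]$dropped, res$dropped)
            }
          }
        }
      }
      work
    })
  }
  structure(list(completions = completions, m = model$m, model = model,
                 variables = variables, seed = model$seed, log = log),
            class = "imputed_stack")
}

#' @export
print.imputed_stack <- function(x, ...) {
  cat("Imputed stack: m =", x$m, "completions of",
      nrow(x$completions[[1]]), "subjects\n")
  inc <- names(x$log)
  if (length(inc)) {
    for (v in inc)
      cat(sprintf("  %s: %d cells imputed (PMM, k = %d)\n", v,
                  length(x$log[[v]]$missing_rows), x$model$k_donors))
  } else cat("  no missing cells; completions identical to input\n")
  invisible(x)
}

#' Extract completed datasets
#'
#' @param stack an `imputed_stack`.
#' @param which completion index, or `NULL` for the full list.
#' @return a data frame or list of data frames.
#' @export
complete_tables <- function(stack, which = NULL) {
  stopifnot(inherits(stack, "imputed_stack"))
  if (is.null(which)) stack$completions else stack$completions[[which]]
}

#' Serialize an imputed stack to a directory of CSV files
#'
#' Writes one `completion_<j>.csv` per completed dataset plus a
#' `provenance.json` capturing the model settings and seed.
#'
#' @param stack an `imputed_stack`; `dir` output directory (created).
#' @return `dir`, invisibly.
#' @export
write_imputed_stack <- function(stack, dir) {
  stopifnot(inherits(stack, "imputed_stack"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (j in seq_len(stack$m))
    write_trial_csv(stack$completions[[j]],
                    file.path(dir, sprintf("completion_%02d.csv", j)))
  prov <- list(m = stack$m, k_donors = stack$model$k_donors,
               chain_iterations = stack$model$chain_iterations,
               proper = stack$model$proper,
               predictors = stack$model$predictors,
               variables = stack$variables,
               seed = stack$seed %||% NA)
  jsonlite::write_json(prov, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
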