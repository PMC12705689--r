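## mediation: regression-based causal mediation for a continuous mediator
## (weight change) and continuous outcome change, reported as natural
## direct/indirect effects, total effect and proportion mediated.

MED_TE_TOL <- 1e-8

## Build the two-arm mediation frame: change, arm indicator (1 = first of
## the pair, 0 = second/reference), mediator, covariates.
mediation_frame <- function(table, spec, arm_pair,
                            mediator = "weight_change") {
  stopifnot(length(arm_pair) == 2)
  m0 <- paste0(spec$outcome, "_m0")
  m12 <- paste0(spec$outcome, "_m12")
  covars <- unique(c(spec$covariates,
                     intersect("weight_m0", names(table))))
  assert_cols(table, c(m0, m12, mediator, "arm", covars))
  tb <- table[table$arm %in% arm_pair, , drop = FALSE]
  df <- data.frame(change = tb[[m12]] - tb[[m0]],
                   arm = as.numeric(tb$arm == arm_pair[1]),
                   mediator = tb[[mediator]],
                   baseline = tb[[m0]])
  for (cv in covars) {
    x <- tb[[cv]]
    df[[cv]] <- if (is.character(x)) factor(x) else x
  }
  df[complete.cases(df), , drop = FALSE]
}

## Point decomposition on a prepared frame.
mediation_decompose <- function(df, interaction = FALSE) {
  med_fit <- lm(mediator ~ . - change, data = df)
  out_fit <- if (interaction)
    lm(change ~ . + arm:mediator, data = df)
  else lm(change ~ ., data = df)
  a <- unname(coef(med_fit)["arm"])
  b <- unname(coef(out_fit)["mediator"])
  cprime <- unname(coef(out_fit)["arm"])
  if (interaction) {
    th3 <- unname(coef(out_fit)["arm:mediator"])
    ## counterfactual formulas for linear models: mediator mean under the
    ## reference arm at the covariate means
    ctrl <- df
    ctrl$arm <- 0
    m_ctrl <- mean(predict(med_fit, ctrl))
    nde <- cprime + th3 * m_ctrl
    nie <- a * (b + th3)
  } else {
    nde <- cprime
    nie <- a * b
  }
  te <- nde + nie
  list(a = a, b = b, cprime = cprime, nde = nde, nie = nie, te = te,
       pm_percent = if (abs(te) > MED_TE_TOL) 100 * nie / te else NA_real_)
}

#' Causal mediation decomposition for one arm pair
#'
#' Mediator model `weight_change ~ arm + covariates` (slope `a`) and
#' outcome model `change ~ arm + weight_change + covariates` (`b`, `c'`)
#' fitted on the complete cases of the two selected arms. In the default
#' linear no-interaction model NIE = a*b, NDE = c', TE = NIE + NDE and the
#' proportion mediated PM = 100 NIE / TE; PM is undefined (NA, with status
#' noted) when |TE| is below tolerance. PM may legitimately fall outside
#' \[0, 100\]% (inconsistent mediation). Covariates are the ANCOVA set
#' (baseline outcome, sex, T2D) plus baseline weight when present.
#'
#' @param table trial table (completed or with missing cells; complete
#'   cases are used).
#' @param spec an [analysis_spec()]; the outcome is the mediated response.
#' @param arm_pair length-2 arm labels, first minus second.
#' @param mediator mediator column.
#' @param interaction include an exposure-mediator interaction and use the
#'   counterfactual formulas evaluated at covariate means.
#' @return list of class `mediation_estimates`: `label`, `a`, `b`,
#'   `cprime`, `nde`, `nie`, `te`, `pm_percent`, `pm_defined`, `n`.
#' @export
fit_mediation <- function(table, spec, arm_pair = c("HND", "UC"),
                          mediator = "weight_change", interaction = FALSE) {
  df <- mediation_frame(table, spec, arm_pair, mediator)
  if (nrow(df) < 4) stop_config("too few complete cases for mediation")
  dec <- mediation_decompose(df, interaction)
  structure(c(list(label = pair_label(arm_pair)), dec,
              list(pm_defined = abs(dec$te) > MED_TE_TOL, n = nrow(df),
                   interaction = interaction)),
            class = "mediation_estimates")
}

#' @export
print.mediation_estimates <- function(x, ...) {
  cat(sprintf("%s: NDE %.3f, NIE %.3f, TE %.3f", x$label, x$nde, x$nie,
              x$te))
  if (x$pm_defined) cat(sprintf(", PM %.0f%%", x$pm_percent))
  else cat(", PM undefined (|TE| ~ 0)")
  cat(sprintf(" [n = %d]\n", x$n))
  invisible(x)
}

#' Bootstrap percentile CIs for the mediation decomposition
#'
#' Subject-level nonparametric bootstrap of the two-arm subset; percentile
#' 95% intervals for NDE, NIE, TE and PM. PM replicates with |TE| below
#' tolerance are excluded from the PM interval and counted; when more than
#' 20% are excluded the result is flagged unstable.
#'
#' @inheritParams fit_mediation
#' @param reps bootstrap replicates (>= 200).
#' @param seed RNG seed.
#' @return `mediation_estimates` augmented with `ci` (matrix with rows
#'   nde/nie/te/pm), `reps`, `pm_excluded`, `status`.
#' @export
bootstrap_mediation_ci <- function(table, spec, arm_pair = c("HND", "UC"),
                                   mediator = "weight_change",
                                   interaction = FALSE, reps = 1000,
                                   seed = NULL) {
  if (reps < 200) stop_config("reps must be >= 200")
  point <- fit_mediation(table, spec, arm_pair, mediator, interaction)
  df <- mediation_frame(table, spec, arm_pair, mediator)
  ## fast resampling path: prebuilt design matrices, lm.fit per replicate
  fast <- !interaction &&
    all(vapply(df[setdiff(names(df), c("change", "arm", "mediator"))],
               function(x) !is.null(fast_code(x)), TRUE))
  if (fast) {
    covs <- setdiff(names(df), c("change", "arm", "mediator"))
    Xc <- do.call(cbind, lapply(df[covs], fast_code))
    Xout <- cbind(1, df$arm, df$mediator, Xc)
    n <- nrow(df)
    one_rep <- function(idx) {
      a <- lm.fit(Xout[idx, -3, drop = FALSE], df$mediator[idx])$coefficients[2]
      oc <- lm.fit(Xout[idx, , drop = FALSE], df$change[idx])$coefficients
      nde <- oc[2]; nie <- a * oc[3]; te <- nde + nie
      c(nde, nie, te,
        if (is.finite(te) && abs(te) > MED_TE_TOL) 100 * nie / te else NA)
    }
  } else {
    one_rep <- function(idx) {
      dec <- tryCatch(mediation_decompose(df[idx, , drop = FALSE],
                                          interaction),
                      error = function(e) NULL)
      if (is.null(dec)) return(c(NA, NA, NA, NA))
      c(dec$nde, dec$nie, dec$te, dec$pm_percent)
    }
  }
  draws <- with_seed(seed, {
    vapply(seq_len(reps), function(i)
      one_rep(sample.int(nrow(df), nrow(df), replace = TRUE)),
      numeric(4))
  })
  rownames(draws) <- c("nde", "nie", "te", "pm")
  qs <- function(v) unname(quantile(v, c(0.025, 0.975), na.rm = TRUE))
  ci <- rbind(nde = qs(draws["nde", ]), nie = qs(draws["nie", ]),
              te = qs(draws["te", ]), pm = qs(draws["pm", ]))
  colnames(ci) <- c("ci_low", "ci_high")
  pm_excluded <- sum(is.na(draws["pm", ]))
  point$ci <- ci
  point$reps <- reps
  point$pm_excluded <- pm_excluded
  point$status <- if (pm_excluded > 0.2 * reps) "unstable-PM" else "ok"
  point
}

#' Mediation under multiple imputation
#'
#' Fits the decomposition on every completed table, pools NDE/NIE/TE by
#' Rubin's rules on the point estimates (between-imputation variance only,
#' as the per-completion sampling variances come from the bootstrap if
#' requested), and recomputes PM from the pooled components — ratios are
#' never pooled directly.
#'
#' @param stack `imputed_stack` or list of completed tables.
#' @inheritParams fit_mediation
#' @return list with pooled `nde`, `nie`, `te`, `pm_percent` and the
#'   per-imputation estimates.
#' @export
mediate_mi <- function(stack, spec, arm_pair = c("HND", "UC"),
                       mediator = "weight_change", interaction = FALSE) {
  tables <- if (inherits(stack, "imputed_stack")) stack$completions else stack
  per <- lapply(tables, fit_mediation, spec = spec, arm_pair = arm_pair,
                mediator = mediator, interaction = interaction)
  nde <- mean(vapply(per, `[[`, 0, "nde"))
  nie <- mean(vapply(per, `[[`, 0, "nie"))
  te <- nde + nie
  list(label = pair_label(arm_pair), nde = nde, nie = nie, te = te,
       pm_percent = if (abs(te) > MED_TE_TOL) 100 * nie / te else NA_real_,
       per_imputation = per)
}
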