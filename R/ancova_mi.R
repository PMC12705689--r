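## ancova_mi: per-imputation baseline-adjusted ANCOVA, Rubin pooling,
## pooled multivariate Wald omnibus test (D1), gatekept pairwise contrasts,
## and Shapiro-Wilk residual routing.

#' Analysis specification for one outcome
#'
#' The analyzed response is the change `<outcome>_m12 - <outcome>_m0`; the
#' linear model regresses it on the arm factor plus the baseline value of
#' the outcome and the listed baseline covariates.
#'
#' @param outcome column stem (e.g. `"liver_fat"`).
#' @param covariates baseline covariate columns besides the baseline
#'   outcome value; default sex and type 2 diabetes status.
#' @param reference reference arm for contrasts.
#' @param alpha two-sided significance level in (0, 1).
#' @return list of class `analysis_spec`.
#' @export
analysis_spec <- function(outcome, covariates = c("sex", "t2d"),
                          reference = "UC", alpha = 0.05) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must lie in (0, 1)")
  structure(list(outcome = outcome, covariates = covariates,
                 reference = reference, alpha = alpha),
            class = "analysis_spec")
}

## Assemble the model frame for one completed table.
ancova_frame <- function(table, spec) {
  m0 <- paste0(spec$outcome, "_m0")
  m12 <- paste0(spec$outcome, "_m12")
  assert_cols(table, c(m0, m12, "arm", spec$covariates))
  arms <- intersect(ARM_LEVELS, unique(as.character(table$arm)))
  lev <- c(intersect(spec$reference, arms), setdiff(arms, spec$reference))
  df <- data.frame(change = table[[m12]] - table[[m0]],
                   arm = factor(table$arm, levels = lev),
                   baseline = table[[m0]])
  for (cv in spec$covariates) {
    x <- table[[cv]]
    df[[cv]] <- if (is.character(x)) factor(x) else x
  }
  df
}

#' Fit the baseline-adjusted ANCOVA on one completed table
#'
#' Least-squares fit of the 12-month change on arm indicators plus the
#' baseline outcome and covariates. Arm contrasts are read off the
#' coefficient differences (they equal estimated-marginal-mean differences
#' in this additive model).
#'
#' @param table completed (no missing modeled cells) trial table.
#' @param spec an [analysis_spec()].
#' @return list of class `ancova_fit`: `fit` (the `lm`), `contrasts`
#'   (data frame with estimate and variance per arm pair), `residuals`,
#'   `dfcom` (residual degrees of freedom), `arm_coefs`, `arm_vcov`.
#' @export
fit_ancova <- function(table, spec) {
  df <- ancova_frame(table, spec)
  if (anyNA(df)) stop_config("fit_ancova requires a completed table")
  if (nlevels(df$arm) < 2) stop_config("need at least 2 arms present")
  fit <- lm(change ~ ., data = df)
  if (anyNA(coef(fit)))
    stop_config("rank-deficient design; aliased: %s",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  V <- vcov(fit)
  lev <- levels(df$arm)
  armcoef <- setNames(rep(0, length(lev)), lev)
  arm_terms <- paste0("arm", lev[-1])
  armcoef[lev[-1]] <- coef(fit)[arm_terms]
  pairs <- utils::combn(lev, 2, simplify = FALSE)
  ## canonical orientation: LCPUFA before HND before UC
  pairs <- lapply(pairs, function(p) p[order(match(p, ARM_LEVELS))])
  contrasts <- do.call(rbind, lapply(pairs, function(p) {
    cv <- setNames(rep(0, length(coef(fit))), names(coef(fit)))
    if (p[1] != lev[1]) cv[paste0("arm", p[1])] <- 1
    if (p[2] != lev[1]) cv[paste0("arm", p[2])] <- -1
    data.frame(label = pair_label(p),
               estimate = armcoef[p[1]] - armcoef[p[2]],
               variance = drop(t(cv) %*% V %*% cv))
  }))
  rownames(contrasts) <- NULL
  structure(list(fit = fit, contrasts = contrasts,
                 residuals = resid(fit), dfcom = fit$df.residual,
                 arm_coefs = armcoef[-1],
                 arm_vcov = V[arm_terms, arm_terms, drop = FALSE]),
            class = "ancova_fit")
}

#' Pool estimates across imputations by Rubin's rules
#'
#' `qbar = mean(estimates)`, within variance `W = mean(variances)`, between
#' variance `B = var(estimates)`, total `T = W + (1 + 1/m) B`, degrees of
#' freedom by the Barnard-Rubin small-sample adjustment, 95% CI
#' `qbar +/- t(df) sqrt(T)` and a two-sided t p-value against 0.
#'
#' @param estimates per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors.
#' @param dfcom complete-data residual degrees of freedom (Inf allowed).
#' @param conf confidence level.
#' @return list of class `pooled_contrast` with fields `qbar`, `W`, `B`,
#'   `T`, `se`, `df`, `ci_low`, `ci_high`, `p`, `m`.
#' @export
pool_rubin <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m < 2) stop_config("Rubin pooling needs m >= 2")
  if (length(variances) != m) stop_config("estimates and variances differ in length")
  qbar <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Tt <- W + (1 + 1 / m) * B
  lambda <- if (Tt > 0) (1 + 1 / m) * B / Tt else 0
  df_old <- if (lambda > 0) (m - 1) / lambda^2 else Inf
  df_obs <- if (is.finite(dfcom))
    (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda) else Inf
  df <- if (is.finite(df_old) && is.finite(df_obs))
    df_old * df_obs / (df_old + df_obs)
  else min(df_old, df_obs)
  se <- sqrt(Tt)
  tcrit <- qt(1 - (1 - conf) / 2, df)
  p <- if (se > 0) 2 * pt(abs(qbar / se), df, lower.tail = FALSE) else
    as.numeric(qbar != 0) * 0
  structure(list(qbar = qbar, W = W, B = B, T = Tt, se = se, df = df,
                 ci_low = qbar - tcrit * se, ci_high = qbar + tcrit * se,
                 p = p, m = m),
            class = "pooled_contrast")
}

#' @export
print.pooled_contrast <- function(x, ...) {
  cat(sprintf("pooled estimate %.4g (95%% CI %.4g, %.4g), p = %.3g [m = %d]\n",
              x$qbar, x$ci_low, x$ci_high, x$p, x$m))
  invisible(x)
}

#' Pooled omnibus arm test (multivariate Wald, D1)
#'
#' Combines the joint 2-degree-of-freedom test of the arm coefficients
#' across imputations by the multivariate Wald rule: with pooled coefficient
#' vector Qbar, average within covariance Ubar and between covariance B,
#' the statistic is `Qbar' Ubar^-1 Qbar / (k (1 + r))` where
#' `r = (1 + 1/m) tr(B Ubar^-1) / k`, referred to an F(k, df2) distribution.
#'
#' @param stack an `imputed_stack` (or list of completed tables).
#' @param spec an [analysis_spec()].
#' @return list of class `global_test`: `statistic`, `df1`, `df2`, `p`,
#'   `significant`, `alpha`, `r`.
#' @export
pooled_global_test <- function(stack, spec) {
  tables <- if (inherits(stack, "imputed_stack")) stack$completions else stack
  fits <- lapply(tables, fit_ancova, spec = spec)
  k <- length(fits[[1]]$arm_coefs)
  if (k < 2) stop_config("omnibus test needs 3 arms (2 arm coefficients)")
  m <- length(fits)
  Q <- do.call(rbind, lapply(fits, `[[`, "arm_coefs"))
  Ubar <- Reduce(`+`, lapply(fits, `[[`, "arm_vcov")) / m
  Qbar <- colMeans(Q)
  B <- if (m > 1) stats::cov(Q) else matrix(0, k, k)
  Uinv <- solve(Ubar)
  r <- (1 + 1 / m) * sum(diag(B %*% Uinv)) / k
  stat <- drop(t(Qbar) %*% Uinv %*% Qbar) / (k * (1 + r))
  t_ <- k * (m - 1)
  df2 <- if (m == 1 || r <= .Machine$double.eps)
    fits[[1]]$dfcom    # single dataset / identical completions: exact F
  else if (t_ > 4) 4 + (t_ - 4) * (1 + (1 - 2 / t_) / r)^2
  else t_ * (1 + 1 / k) * (1 + 1 / r)^2 / 2
  p <- pf(stat, k, df2, lower.tail = FALSE)
  structure(list(statistic = stat, df1 = k, df2 = df2, p = p,
                 significant = p < spec$alpha, alpha = spec$alpha, r = r,
                 m = m),
            class = "global_test")
}

#' @export
print.global_test <- function(x, ...) {
  cat(sprintf("pooled omnibus F(%d, %.1f) = %.3f, p = %.4g (%s at alpha = %g)\n",
              x$df1, x$df2, x$statistic, x$p,
              if (x$significant) "significant" else "not significant", x$alpha))
  invisible(x)
}

#' Rubin-pooled pairwise arm contrasts
#'
#' Each pair is, by default, refit on the two-arm subset of every completed
#' table with the same covariates (`refit = FALSE` instead extracts the
#' contrast from the full three-arm fit).
#'
#' @param stack `imputed_stack` or list of completed tables.
#' @param spec an [analysis_spec()].
#' @param pairs list of 2-vectors of arm labels.
#' @param refit refit per pair (default) or extract from the full model.
#' @return data frame, one row per pair: `label`, `estimate`, `se`,
#'   `ci_low`, `ci_high`, `df`, `p`.
#' @export
pool_ancova_contrasts <- function(stack, spec, pairs = ARM_PAIRS,
                                  refit = TRUE) {
  tables <- if (inherits(stack, "imputed_stack")) stack$completions else stack
  rows <- lapply(pairs, function(p) {
    lbl <- pair_label(p)
    per <- lapply(tables, function(tb) {
      if (refit) tb <- tb[tb$arm %in% p, , drop = FALSE]
      ft <- fit_ancova(tb, spec)
      ct <- ft$contrasts[ft$contrasts$label %in%
                           c(lbl, pair_label(rev(p))), , drop = FALSE]
      est <- ct$estimate[1]
      if (ct$label[1] != lbl) est <- -est
      c(est = est, var = ct$variance[1], dfcom = ft$dfcom)
    })
    per <- do.call(rbind, per)
    pc <- pool_rubin(per[, "est"], per[, "var"], dfcom = per[1, "dfcom"])
    data.frame(label = lbl, estimate = pc$qbar, se = pc$se,
               ci_low = pc$ci_low, ci_high = pc$ci_high, df = pc$df,
               p = pc$p)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Gatekept pairwise comparisons
#'
#' Pairwise contrasts are released only when the pooled omnibus test is
#' significant at its alpha; otherwise an empty set with status
#' `"gatekept"` is returned. This sequential strategy preserves the
#' familywise error rate at the nominal level for three groups.
#'
#' @param global a [pooled_global_test()] result computed on the same
#'   stack and spec.
#' @inheritParams pool_ancova_contrasts
#' @return list of class `gatekeep_result`: `status` (`"released"` or
#'   `"gatekept"`), `global`, `contrasts` (possibly 0-row data frame).
#' @export
gatekeep_pairwise <- function(global, stack, spec, refit = TRUE) {
  stopifnot(inherits(global, "global_test"))
  if (!global$significant) {
    empty <- data.frame(label = character(), estimate = numeric(),
                        se = numeric(), ci_low = numeric(),
                        ci_high = numeric(), df = numeric(), p = numeric())
    return(structure(list(status = "gatekept", global = global,
                          contrasts = empty), class = "gatekeep_result"))
  }
  ct <- pool_ancova_contrasts(stack, spec, refit = refit)
  structure(list(status = "released", global = global, contrasts = ct),
            class = "gatekeep_result")
}

#' Shapiro-Wilk residual normality check across imputations
#'
#' Computes the Shapiro-Wilk W on the ANCOVA residuals of every completed
#' table; the branch decision uses the median W with the strict rule
#' `gaussian = (median W > 0.95)`.
#'
#' @inheritParams pool_ancova_contrasts
#' @param threshold W threshold; strictly greater counts as Gaussian.
#' @return list of class `normality_check`: `W` (per imputation),
#'   `summary_W` (median), `gaussian`.
#' @export
residual_normality <- function(stack, spec, threshold = 0.95) {
  tables <- if (inherits(stack, "imputed_stack")) stack$completions else stack
  W <- vapply(tables, function(tb) {
    r <- fit_ancova(tb, spec)$residuals
    if (length(r) < 3) stop_config("Shapiro-Wilk undefined for n < 3")
    shapiro.test(r)$statistic
  }, 0)
  sw <- median(W)
  structure(list(W = unname(W), summary_W = sw, gaussian = sw > threshold,
                 threshold = threshold),
            class = "normality_check")
}
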