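## nonparam: covariate adjustment by the residual method (arm omitted from
## the fit), Kruskal-Wallis testing, bootstrap-then-impute percentile CIs
## for adjusted median differences, and Hodges-Lehmann per-protocol
## estimation.

#' Covariate-adjusted change values (residual method)
#'
#' Fits the same linear model as the ANCOVA but with the arm factor
#' omitted, and returns `residual + mean(change)` — a location-preserving
#' covariate adjustment whose group medians estimate adjusted marginal
#' medians. Arm labels play no role in the fit, so relabeling arms leaves
#' the output unchanged.
#'
#' @param table completed trial table.
#' @param spec an [analysis_spec()].
#' @return numeric vector, one adjusted change per subject.
#' @export
adjusted_residuals <- function(table, spec) {
  df <- ancova_frame(table, spec)
  df$arm <- NULL
  if (anyNA(df)) stop_config("adjusted_residuals requires a completed table")
  fit <- lm(change ~ ., data = df)
  if (anyNA(coef(fit)))
    stop_config("rank-deficient adjustment design; aliased: %s",
                paste(names(coef(fit))[is.na(coef(fit))], collapse = ", "))
  unname(resid(fit) + mean(df$change))
}

#' Kruskal-Wallis rank test
#'
#' Midrank-based H with tie correction, referred to chi-square with
#' (number of groups - 1) degrees of freedom. All-equal samples return
#' H = 0 by the tie-correction convention.
#'
#' @param values numeric vector; `groups` parallel group labels.
#' @return list with `H`, `df`, `p`.
#' @export
kruskal_wallis <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop_config("need at least 2 groups")
  if (any(table(groups) == 0)) stop_config("empty group")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1))
  kt <- kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}

#' Kruskal-Wallis on adjusted residuals across an imputed stack
#'
#' Runs the residual-method Kruskal-Wallis test on every completed table
#' and pools the p-values: `rule = "median_p"` (default) takes the median
#' per-imputation p; `"mean_z"` averages probit-transformed p-values.
#'
#' @param stack `imputed_stack` or list of completed tables.
#' @param spec an [analysis_spec()].
#' @param rule pooling rule.
#' @return list of class `mi_kw`: `p`, `per_imputation_p`, `rule`, `H`.
#' @export
mi_kw_test <- function(stack, spec, rule = c("median_p", "mean_z")) {
  rule <- match.arg(rule)
  tables <- if (inherits(stack, "imputed_stack")) stack$completions else stack
  res <- lapply(tables, function(tb) {
    adj <- adjusted_residuals(tb, spec)
    kruskal_wallis(adj, tb$arm)
  })
  ps <- vapply(res, `[[`, 0, "p")
  p <- switch(rule,
              median_p = median(ps),
              mean_z = pnorm(mean(stats::qnorm(pmin(pmax(ps, 1e-15),
                                                    1 - 1e-15)))))
  structure(list(p = p, per_imputation_p = ps, rule = rule,
                 H = vapply(res, `[[`, 0, "H")),
            class = "mi_kw")
}

## numeric coding of a two-level (or numeric) covariate for fast fits
fast_code <- function(x) {
  if (is.numeric(x)) return(x)
  if (is.logical(x)) return(as.numeric(x))
  u <- unique(x)
  if (length(u) > 2) return(NULL)   # caller falls back to model.matrix
  as.numeric(x == u[1])
}

## group medians of adjusted residuals -> pairwise differences; uses a
## direct .lm.fit when all covariates are binary/numeric (the hot path of
## the bootstrap loop), identical results to adjusted_residuals()
adjusted_median_diffs <- function(table, spec, pairs) {
  m0 <- table[[paste0(spec$outcome, "_m0")]]
  y <- table[[paste0(spec$outcome, "_m12")]] - m0
  cov_cols <- lapply(spec$covariates, function(cv) fast_code(table[[cv]]))
  adj <- if (!any(vapply(cov_cols, is.null, TRUE))) {
    X <- cbind(1, m0, do.call(cbind, cov_cols))
    .lm.fit(X, y)$residuals + mean(y)
  } else adjusted_residuals(table, spec)
  med <- tapply(adj, factor(table$arm), median)
  vapply(pairs, function(p) unname(med[p[1]] - med[p[2]]), 0)
}

#' Bootstrap-then-impute adjusted median contrasts
#'
#' For each of `B` bootstrap resamples of subjects (household pairs are
#' resampled as one unit when `household_id` is present), the resample is
#' multiply imputed `m_per_bootstrap` times, the adjusted median difference
#' (difference of arm medians of [adjusted_residuals()]) is computed per
#' completion and averaged across completions, giving one bootstrap
#' replicate per arm pair. The point estimate is the replicate mean, the
#' 95% CI the percentile interval, and the p-value
#' `2 min(P(rep <= 0), P(rep >= 0))` clamped to `[2/B, 1]`. Resamples
#' missing an entire arm are redrawn (count reported).
#'
#' @param table trial table, possibly with missing month-12 outcomes.
#' @param spec an [analysis_spec()].
#' @param B number of bootstrap resamples (>= 100; trial preset 10,000).
#' @param m_per_bootstrap imputations per resample (trial preset 20).
#' @param seed RNG seed; identical seeds give identical CIs.
#' @param chain_iterations chained-equation sweeps per imputation.
#' @param k_donors donors per missing cell.
#' @param pairs arm pairs to contrast.
#' @return data frame of class `median_contrasts`: one row per pair with
#'   `label`, `estimate`, `ci_low`, `ci_high`, `p`; attributes `B`,
#'   `m_per_bootstrap`, `redraws`, `seed`.
#' @export
boot_impute_median_contrasts <- function(table, spec, B = 500,
                                         m_per_bootstrap = 2, seed = NULL,
                                         chain_iterations = 5, k_donors = 5,
                                         pairs = ARM_PAIRS) {
  if (B < 100) stop_config("B must be >= 100 for a reported CI")
  pairs <- Filter(function(p) all(p %in% table$arm), pairs)
  if (!length(pairs)) stop_config("no requested arm pair present in table")
  needed <- c(paste0(spec$outcome, "_m0"), paste0(spec$outcome, "_m12"),
              spec$covariates)
  hh <- if ("household_id" %in% names(table)) table$household_id else
    rep(NA, nrow(table))
  unit <- ifelse(is.na(hh), paste0("s", seq_len(nrow(table))),
                 paste0("h", hh))
  unit_rows <- split(seq_len(nrow(table)), unit)
  n_units <- length(unit_rows)
  redraws <- 0L
  reps <- matrix(NA_real_, B, length(pairs))
  with_seed(seed, {
    for (b in seq_len(B)) {
      repeat {
        take <- sample.int(n_units, n_units, replace = TRUE)
        rows <- unlist(unit_rows[take], use.names = FALSE)
        boot <- table[rows, , drop = FALSE]
        if (all(unlist(pairs) %in% boot$arm)) break
        redraws <- redraws + 1L
      }
      boot$id <- seq_len(nrow(boot))
      to_impute <- needed[vapply(needed, function(v) anyNA(boot[[v]]), TRUE)]
      vals <- if (length(to_impute)) {
        mod <- imputation_model(
          predictors = intersect(c("arm", "bmi_m0", "age", "sex", "t2d"),
                                 names(boot)),
          m = max(m_per_bootstrap, 2), chain_iterations = chain_iterations,
          k_donors = k_donors, proper = TRUE, seed = NULL)
        stk <- impute_mice_pmm(boot, mod, variables = to_impute)
        per <- vapply(stk$completions[seq_len(m_per_bootstrap)],
                      adjusted_median_diffs, numeric(length(pairs)),
                      spec = spec, pairs = pairs)
        if (length(pairs) == 1L) mean(per) else rowMeans(matrix(per, nrow = length(pairs)))
      } else {
        adjusted_median_diffs(boot, spec, pairs)
      }
      reps[b, ] <- vals
    }
  })
  out <- do.call(rbind, lapply(seq_along(pairs), function(i) {
    r <- reps[, i]
    ci <- unname(quantile(r, c(0.025, 0.975), type = 7))
    p <- 2 * min(mean(r <= 0), mean(r >= 0))
    data.frame(label = pair_label(pairs[[i]]), estimate = mean(r),
               ci_low = ci[1], ci_high = ci[2],
               p = min(max(p, 2 / B), 1))
  }))
  rownames(out) <- NULL
  structure(out, class = c("median_contrasts", "data.frame"),
            B = B, m_per_bootstrap = m_per_bootstrap, redraws = redraws,
            seed = seed)
}

#' Hodges-Lehmann location-shift estimate with Wilcoxon CI
#'
#' Point estimate: the median of all `length(x) * length(y)` pairwise
#' differences `x_i - y_j`. The confidence interval inverts the Wilcoxon
#' rank-sum test.
#'
#' @param x,y nonempty numeric samples.
#' @param conf confidence level.
#' @return list with `estimate`, `ci_low`, `ci_high`.
#' @export
hodges_lehmann <- function(x, y, conf = 0.95) {
  if (!length(x) || !length(y)) stop_config("empty sample")
  est <- median(outer(x, y, `-`))
  wt <- suppressWarnings(wilcox.test(x, y, conf.int = TRUE,
                                     conf.level = conf))
  list(estimate = est, ci_low = unname(wt$conf.int[1]),
       ci_high = unname(wt$conf.int[2]))
}
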