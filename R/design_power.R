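## design_power: sample-size and power arithmetic for the two-group
## comparison the trial was designed around (difference 2 units, SD 3,
## alpha 0.05 two-sided, power 0.80, 25% attrition).

#' Design specification
#'
#' @param delta detectable difference (outcome units).
#' @param sd outcome standard deviation (> 0).
#' @param alpha two-sided significance level.
#' @param power target power.
#' @param dropout_rate anticipated attrition in \[0, 1).
#' @return list of class `design_spec`.
#' @export
design_spec <- function(delta = 2, sd = 3, alpha = 0.05, power = 0.80,
                        dropout_rate = 0.25) {
  if (sd <= 0) stop_config("sd must be > 0")
  for (v in c(alpha, power)) if (v <= 0 || v >= 1)
    stop_config("alpha and power must lie in (0, 1)")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate must lie in [0, 1)")
  structure(list(delta = delta, sd = sd, alpha = alpha, power = power,
                 dropout_rate = dropout_rate), class = "design_spec")
}

#' Lehr's quick sample-size formula
#'
#' `ceiling(16 / (delta/sd)^2)` per group — the rule-of-thumb
#' approximation for a two-sided alpha 0.05, power 0.80 two-sample
#' comparison.
#'
#' @param delta nonzero difference; `sd` > 0.
#' @return integer subjects per group.
#' @export
lehr_n <- function(delta, sd) {
  if (delta == 0) stop_config("delta must be nonzero")
  if (sd <= 0) stop_config("sd must be > 0")
  as.integer(ceiling(16 / (delta / sd)^2))
}

## Exact two-sided two-sample t-test power at per-group n.
t_power <- function(n, delta, sd, alpha) {
  df <- 2 * n - 2
  ncp <- (delta / sd) * sqrt(n / 2)
  crit <- qt(1 - alpha / 2, df)
  pt(crit, df, ncp, lower.tail = FALSE) + pt(-crit, df, ncp)
}

#' Per-group sample size by the noncentral-t power function
#'
#' Smallest integer n per group for which the two-sided two-sample t-test
#' at level `alpha` attains the requested power, via the noncentral-t
#' distribution with noncentrality `(delta/sd) sqrt(n/2)` and 2n-2 degrees
#' of freedom. At the classic design point (2, 3, 0.05, 0.80) this yields
#' 37, one more than [lehr_n()]'s 36.
#'
#' @inheritParams design_spec
#' @return integer subjects per group.
#' @export
power_n_t <- function(delta, sd, alpha = 0.05, power = 0.80) {
  if (delta == 0) stop_config("delta must be nonzero")
  if (power <= alpha) stop_config("power must exceed alpha")
  n <- 2L
  while (t_power(n, delta, sd, alpha) < power) {
    n <- n + 1L
    if (n > 1e7) stop_config("sample size search did not converge")
  }
  n
}

#' Inflate a per-group sample size for attrition
#'
#' `ceiling(n / (1 - dropout_rate))`.
#'
#' @param n evaluable subjects per group; `dropout_rate` in \[0, 1).
#' @return enrolled subjects per group.
#' @export
inflate_attrition <- function(n, dropout_rate) {
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop_config("dropout_rate must lie in [0, 1)")
  as.integer(ceiling(n / (1 - dropout_rate)))
}

#' Empirical power of the two-sample t-test by simulation
#'
#' Simulates `reps` pairs of Normal samples (difference `delta`, common SD
#' `sd`) of size `n_per_group` and reports the fraction of two-sided
#' t-tests rejecting at `alpha`, with its binomial Monte-Carlo SE.
#'
#' @param design a [design_spec()].
#' @param n_per_group per-group sample size.
#' @param reps simulation replicates (>= 1000).
#' @param seed RNG seed.
#' @return data frame of class `simulation_report` (scenario, reps,
#'   metric, value, mc_se, seed).
#' @export
empirical_power <- function(design = design_spec(), n_per_group = 37,
                            reps = 10000, seed = 1) {
  if (reps < 1000) stop_config("reps must be >= 1000")
  n <- n_per_group
  rej <- with_seed(seed, {
    x <- matrix(rnorm(reps * n, 0, design$sd), n)
    y <- matrix(rnorm(reps * n, design$delta, design$sd), n)
    mx <- colMeans(x); my <- colMeans(y)
    vx <- colSums((x - rep(mx, each = n))^2) / (n - 1)
    vy <- colSums((y - rep(my, each = n))^2) / (n - 1)
    df <- 2 * n - 2        # equal-variance two-sample t
    sp <- sqrt(((n - 1) * vx + (n - 1) * vy) / df)
    tt <- (my - mx) / (sp * sqrt(2 / n))
    mean(abs(tt) > qt(1 - design$alpha / 2, df))
  })
  simulation_report("two_sample_power", reps, "rejection_rate", rej, seed)
}

## shared constructor for simulation summaries
simulation_report <- function(scenario, reps, metric, value, seed) {
  if (reps < 100) stop_config("reps must be >= 100")
  stopifnot(metric %in% c("rejection_rate", "coverage", "bias", "rmse"))
  mc_se <- if (metric %in% c("rejection_rate", "coverage"))
    sqrt(value * (1 - value) / reps) else NA_real_
  structure(data.frame(scenario = scenario, reps = reps, metric = metric,
                       value = value, mc_se = mc_se,
                       seed = seed %||% NA_integer_),
            class = c("simulation_report", "data.frame"))
}
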