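---
title: "Analyzing a three-arm dietary trial with multiply imputed ANCOVA"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing a three-arm dietary trial with multiply imputed ANCOVA}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`trialmi` implements the complete statistical pipeline of a three-arm
parallel-group randomized dietary trial with continuous outcomes measured
at baseline (month 0) and follow-up (month 12): two experimental diets
(`LCPUFA`, a low-carbohydrate diet high in polyunsaturated fat, and `HND`,
a healthy Nordic diet) against usual care (`UC`), in a population with
prediabetes or type 2 diabetes, with liver fat (MRI proton-density fat
fraction, %) as the primary outcome. Because individual-level trial data
of this kind cannot be shared, the package pairs the analysis machinery
with a synthetic-trial generator that emulates the design — so that every
statistical property the pipeline claims can be demonstrated on data whose
truth is known.

## The analysis model

For each outcome $Y$ the analyzed response is the change
$\Delta = Y_{12} - Y_0$. The parametric branch fits the ANCOVA

$$\Delta_i = \beta_0 + \beta_1\,\mathrm{LCPUFA}_i + \beta_2\,\mathrm{HND}_i
 + \beta_3 Y_{0,i} + \beta_4\,\mathrm{sex}_i + \beta_5\,\mathrm{T2D}_i
 + \varepsilon_i,$$

so arm contrasts are differences of the arm coefficients and coincide with
estimated-marginal-mean differences (the model is additive). Missing
outcome or baseline cells are multiply imputed ($m = 20$ by default) by
chained equations with predictive mean matching, each completed dataset is
fitted, and estimates are pooled by Rubin's rules: $\bar q$ the mean
estimate, $W$ the mean squared standard error, $B$ the between-imputation
variance, $T = W + (1 + 1/m)B$, with Barnard–Rubin degrees of freedom.

Inference is *gatekept*: the joint 2-df arm hypothesis is tested first by
the multivariate Wald (D1) combination rule, and the three pairwise
contrasts (each refit on its two-arm subset) are released only when the
omnibus test is significant at $\alpha = 0.05$. This sequential scheme
preserves the familywise error rate for three groups without further
multiplicity adjustment; `simulate_operating_characteristics("null_fwer")`
verifies it by direct simulation.

Routing between branches follows a Shapiro–Wilk check of the ANCOVA
residuals in every completed dataset, summarized as the median $W$ across
imputations with the strict rule "Gaussian iff median $W > 0.95$". When
the rule fails, the nonparametric branch runs: the same linear model is
fitted *without* the arm factor, residuals (plus the grand mean change, so
location is preserved) become covariate-adjusted changes, a
Kruskal–Wallis test on them plays the role of the omnibus gate, and
adjusted median differences between arms get percentile confidence
intervals from a bootstrap-then-impute scheme — resample subjects
(household pairs as one unit), impute each resample, average the adjusted
median difference over the imputations, and repeat. In the per-protocol
population (complete cases) the nonparametric contrast is the
Hodges–Lehmann estimator with a Wilcoxon-inversion interval instead.

A post-hoc causal mediation analysis treats 12-month weight change as the
mediator of the diet effect on liver fat: a linear mediator model
($a$ = arm effect on weight change) and a linear outcome model
($b$ = weight-change slope, $c'$ = direct effect) give
$\mathrm{NIE} = ab$, $\mathrm{NDE} = c'$, $\mathrm{TE} = ab + c'$ and the
proportion mediated $\mathrm{PM} = 100\,\mathrm{NIE}/\mathrm{TE}$. PM is
a ratio: it is undefined when $|\mathrm{TE}|$ is near zero and can
legitimately fall outside $[0, 100]\%$ (inconsistent mediation); the
bootstrap excludes and counts degenerate replicates.

## What the generator emulates — and what it does not

`generate_trial()` reproduces the design skeleton: 150 subjects, 1:1:1
allocation by permuted blocks stratified by sex and type 2 diabetes
status, four co-randomized household pairs, seven outcomes on the scale of
the emulated trial's baseline tables, a weight-change mediator path, and
missing-at-random blanking of month-12 values (14% for liver fat, 5–7%
elsewhere) driven logistically by baseline BMI and T2D with the intercept
solved numerically to hit the marginal rate.

Key default choices, made once:

* **Skewed outcomes.** Liver fat, glucose, triglycerides and CRP use
  lognormal baselines (the trial reported them as median (IQR)); changes
  are additive on the natural scale and month-12 values are truncated at
  zero. Truncation makes the realized mean contrast slightly smaller in
  magnitude than the planted parameter for liver fat (about 0.1–0.15
  percentage units at the default settings) — the recovery tests therefore
  check the pipeline against complete-data estimates (imputation
  faithfulness) and by CI coverage of the planted value, and use the
  untruncated weight outcome for the tight mean-recovery check.
* **Planted effects.** Total contrasts versus usual care are calibrated to
  the emulated trial's headline numbers: liver fat −1.46% (LCPUFA) and
  −1.76% (HND); weight change −0.31 and −2.77 kg. The liver-fat mediator
  slope (0.36 % per kg) makes the mediated share of the HND liver-fat
  effect roughly half, matching the reported proportion mediated.
* **Mediator noise.** Weight-change residual SD 4.5 kg, consistent with
  the per-arm confidence intervals of the emulated trial.
* **MAR mechanism.** The trial states MAR but no mechanism; logistic
  dependence on baseline BMI (+0.08 per kg/m²) and T2D (+0.4) is a
  defensible mechanism that keeps missingness ignorable given the
  imputation model.
* **Household pairs.** No within-pair correlation by default (SD 0,
  configurable): the design document gives none, and a zero default keeps
  the pair-exclusion sensitivity analysis interpretable as a pure
  subset change.
* **Month-6 BMI** is linear interpolation plus noise, present only so the
  sensitivity imputation model with month-6/12 BMI predictors can run.

Passing tests on these synthetic trials demonstrate the pipeline's
*statistical* properties (error rates, coverage, recovery under MAR); they
do not certify behavior under features the generator omits — informative
dropout, measurement drift, non-ignorable missingness, or real
correlation structure among the seven outcomes beyond the shared
weight-change path.

## Imputation details

Each incomplete variable is regressed on all other model-set variables
(default predictor set: diet group, BMI, age, sex, T2D status, plus the
baseline value and the outcome itself, mirroring the emulated trial's
imputation model). Coefficients are drawn from their posterior
(`proper = TRUE`), predictions are computed for missing cases with the
drawn coefficients and for observed cases with the least-squares ones
(type-1 matching), and each missing cell copies the observed value of one
of the `k_donors = 5` nearest-prediction donors, chosen uniformly.
`chain_iterations = 10` sweeps are run; when only one variable is
incomplete a single sweep is used — with fully observed predictors the
sweeps are independent redraws, so this is distributionally identical.
`k = 5` and 10 iterations are the method's conventional defaults; the
trial names the method but no settings. Binary variables (the baseline
steatosis flag) are imputed by PMM on their 0/1 coding, which can only
return observed 0/1 values.

Two behaviors of PMM worth knowing: imputed values are always observed
donor values (an invariant the tests assert), and the donor-matching noise
adds between-imputation variance beyond the parameter draw, which makes
the pooled D1 omnibus test mildly conservative at small $m$ (empirical
size ≈ 0.02 at $m = 5$ with 14% missingness, versus ≈ 0.05–0.06 when the
same pooling rule is fed a pure normal-model imputation). Conservative
means the gatekeeper's familywise-error guarantee is preserved.

## Numerical choices

* Pairwise contrasts are refit on each two-arm subset (matching the
  emulated analysis description) rather than extracted from the three-arm
  fit; `refit = FALSE` exposes the latter, under which transitivity
  $(\mathrm{LCPUFA{-}UC}) - (\mathrm{HND{-}UC}) = \mathrm{LCPUFA{-}HND}$
  holds exactly.
* Degrees of freedom: Barnard–Rubin for scalar pooling; the Li–
  Raghunathan–Rubin $\mathrm{df}_2$ for D1, collapsing to the
  complete-data residual df when the between variance vanishes.
* Kruskal–Wallis p-values across imputations are pooled as the median p
  (a `mean_z` alternative is provided); the emulated trial applied the
  test under MI without stating a combination rule.
* The bootstrap p-value is $2\min(\Pr(\hat\theta^* \le 0),
  \Pr(\hat\theta^* \ge 0))$ clamped to $[2/B, 1]$; resamples missing an
  entire arm are redrawn and counted.
* "Estimated marginal median difference" is operationalized as the
  difference of arm medians of the location-preserved adjusted residuals;
  under symmetric errors this estimates the same quantity as the
  parametric contrast.
* With $m = 2$ imputations per bootstrap resample (the desk-scale
  preset), imputation noise contributes to the replicate spread, so
  percentile intervals over-cover somewhat (empirically ≈ 0.99 at a
  nominal 0.95); the trial-scale preset ($B = 10{,}000$, $m = 20$) shrinks
  this. The nesting of "10,000 bootstraps, 20 imputations" is read as 20
  per bootstrap; the total-of-20 reading is possible but not assumed
  anywhere else.
* Mediation covariates mirror the ANCOVA set plus baseline weight; the
  emulated trial does not enumerate its mediation covariates, so this is
  an assumption of the package. Under MI, NDE/NIE/TE are pooled and PM is
  recomputed from the pooled components — ratios are never pooled.
* Sample-size arithmetic: Lehr's rule gives
  $\lceil 16/(2/3)^2 \rceil = 36$ per group, while the noncentral-t
  calculation gives 37 — the number the emulated trial reports despite
  attributing it to Lehr. Both are exported; the discrepancy is surfaced
  rather than reconciled.
* Subgroup analyses drop the stratifier from the covariate set, impute
  separately per stratum, and (for the steatosis-status subgroup) impute
  the status flag first. When a stratifier has missing values the first
  completion defines the strata — a single-imputation simplification,
  acceptable because the flag has few missing values by design.

## Validation problem sizes

The package validates itself at desk scale: familywise error on 2,000
null trials, test size on 1,000, power points on 200–10,000 replicates,
bootstrap coverage on 200 trials at $B = 500$, $m = 2$, and planted-effect
recovery on 200 trials at $m = 5$. Trial-scale settings
($m = 20$, $B = 10{,}000$) are configuration presets on the same code
paths.

## A worked run

```{r, eval = FALSE}
library(trialmi)
tab <- generate_trial(seed = 1)
cfg <- run_config(outcomes = c("liver_fat", "weight"), m = 20, B = 500,
                  seed = 1)
report <- run_primary_analysis(tab, cfg)
print(report)
write_report(report, "primary_report.json")
```

## Known limitations

Single mediator, no exposure–mediator confounding sensitivity analysis;
no multilevel imputation for household clustering (pairs are handled by
cluster resampling and by the exclusion sensitivity analysis); dropout is
instantaneous MAR blanking, not a longitudinal process; and the
nonparametric branch's median estimand differs from the mean estimand
under asymmetric errors — which is precisely when that branch fires, so
parametric and nonparametric contrasts should not be numerically compared
on skewed outcomes.
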