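---
title: "Modelling adverse birth outcomes as a mediated equation system"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adverse birth outcomes as a mediated equation system}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsembirth)
```

## The statistical model

`gsembirth` fits a recursive system of Bernoulli regressions for three
adverse birth outcomes. Preterm birth (PB) is an *observed mediator*: it
is an outcome of the pollutant exposures in its own equation and a
predictor in the low-birthweight (LBW) and small-for-gestational-age
(SGA) equations. On the link scale,

$$g\{P(\mathrm{PB}_i = 1)\} = \alpha_1 + \Gamma_1' x_i,$$
$$g\{P(\mathrm{LBW}_i = 1 \mid \mathrm{PB}_i)\} = \alpha_2 +
  \beta_2\,\mathrm{PB}_i + \Gamma_2' x_i,$$
$$g\{P(\mathrm{SGA}_i = 1 \mid \mathrm{PB}_i)\} = \alpha_3 +
  \beta_3\,\mathrm{PB}_i + \Gamma_3' x_i,$$

with $x_i$ the exposures (PM2.5, SO2, NOx in µg/m³) and the adjustment
covariates. The default link is the complementary log–log,
$g(p) = \log(-\log(1-p))$, an asymmetric link whose inverse at zero is
$1 - e^{-1} \approx 0.632$; logit and probit are available and the three
families are compared by AIC/BIC (`compare_links()`, minimum AIC, ties
broken toward lower BIC and then lexicographically).

Because the endogenous graph is acyclic and the mediator observed, the
joint likelihood factorises over equations. `fit_system()` exploits that
separability — each equation is maximised by Newton-type (Fisher-scoring)
iterations with step-halving — while exposing the joint log-likelihood,
stacked coefficient vector and block-diagonal joint covariance. The
separability identity (joint log-likelihood equals the sum of
per-equation log-likelihoods, to 1e-8) is asserted in the test suite, so
the computational shortcut is verified rather than assumed.

### Mediation decomposition

Indirect effects follow the product-of-coefficients convention: the
indirect effect of exposure $e$ on outcome $y$ through a path is the
product of the path's edge coefficients, paths are enumerated by
depth-first search over the acyclic graph, and the total effect is the
direct coefficient plus the summed indirect products. All sums live on
the linear-predictor scale; exponentiation is display-only ("effect
ratios", odds ratios under the logit link). This is deliberately *not* a
counterfactual (natural direct/indirect) decomposition: under nonlinear
links the coefficient-product rule does not correspond to a potential-
outcome estimand, and the package documents rather than hides that
limitation. Standard errors for products come from the delta method with
analytic gradients ($\partial(ab)/\partial a = b$, etc.) on the joint
covariance; `bootstrap_ci()` provides a nonparametric companion
(record or whole-cluster resampling, percentile intervals, failed
replicates counted and capped at 10%).

### Cluster-robust covariance

Standard errors can be clustered on residential location via the
sandwich estimator $A^{-1} B A^{-1}$, with $A$ the observed information
and $B$ the outer product of within-cluster score sums
(`sandwich_covariance()` per equation, `system_sandwich()` jointly, the
latter capturing cross-equation dependence through shared clusters).
Cluster granularity is configurable: the generator emits both a
six-level residential `community` and the binary `south_durban` label;
the pipeline clusters on `community` by default because two clusters
make the variance estimator degenerate. No small-sample factor is
applied by default; the G/(G−1)·(n−1)/(n−k) correction is available as
an option.

### The optional latent factor

A shared record-level factor $\eta^* \sim N(0, \psi)$ with loadings
$\lambda$ (first fixed to 1) can enter all three linear predictors,
capturing unmeasured maternal frailty. The marginal likelihood
integrates $\eta^*$ out per record by mode-curvature adaptive
Gauss–Hermite quadrature: the grid is recentred at the mode of the
per-record log joint density (safeguarded Newton) and rescaled by the
inverse square root of its negative curvature. Seven nodes are the
default; the per-record agreement between the 7-node adaptive rule and a
201-node nonadaptive reference is asserted to 1e-5 in the tests at
moderate heterogeneity ($\psi = 0.5$). Accuracy degrades as
$\lambda\sqrt{\psi}$ grows (the integrand becomes skewed), and a coarse
rule can even *overstate* the likelihood in extreme-loading corners.
`fit_latent_system()` therefore applies a stability safeguard: after the
optimiser converges it re-evaluates the optimum under a rule twice as
dense and refits with more nodes (15, then 31) until the two agree
within 1e-3. The outer optimisation is L-BFGS-B over coefficients, free
loadings and $\log\sqrt\psi$, with the analytic marginal score
(posterior-weighted complete-data score over the quadrature nodes).

Two properties of this model deserve honesty. First, $\hat\psi$ near
zero is weakly identified with only three binary indicators: the
likelihood is nearly flat, so on data generated with $\psi = 0$ the
point estimate scatters well above zero even at $n = 2000$ while the
likelihood-ratio improvement stays negligible. Second, the mediator edge
$\beta_2$ and the shared factor trade off along a near-flat ridge:
cross-outcome association can be booked to either. The tests therefore
assess the latent model on the likelihood-ratio scale and against its
own reported uncertainty rather than by point-estimate closeness, and a
$\hat\psi$ at the boundary is reported with a flag, not an error.

## The synthetic cohort generator

The restricted study data cannot ship, so the generator *is* the study
environment and every downstream guarantee is calibrated against it.

* **Structure emulated.** 996 enrolled records; exclusion flags with the
  exact published counts (2 multiple pregnancies, 55 miscarriages,
  25 stillbirths, 2 terminations, 225 relocations, 31 postdate births),
  leaving 656 analysed; exposures with the published medians and ranges
  (PM2.5 13.0 in 8.9–14.1, SO2 2.8 in 2.1–5.9, NOx 34.4 in
  2.5–45.4 µg/m³); outcome prevalences implied by the published case
  counts (113/656, 93/656, 72/656); preterm birth generated first and
  the other outcomes conditional on it, matching the mediation
  structure.
* **Exposure marginals** are Beta distributions scaled to
  [min, max] with shapes solved so the distribution's median matches the
  published median (total shape 4 by default; bounded support mirrors a
  bounded land-use-regression prediction surface). A Gaussian copula
  imposes the rank-correlation structure; the latent Gaussian
  correlation is $2\sin(\pi\rho_s/6)$, the exact Spearman-to-Pearson map
  for the bivariate normal, so the *rank* correlations are the
  calibrated quantity. The default magnitudes (0.4 NOx–PM2.5, 0.3
  NOx–SO2, −0.1 PM2.5–SO2) are package choices consistent with the
  qualitative published pattern ("modest positive", "weakly negative");
  they are config values, not published numbers.
* **True coefficients** default to the logs of the published adjusted
  odds ratios, read as printed; the two mediator edges have no published
  value and are set to plausibly strong 1.5 (PB→LBW) and 1.2 (PB→SGA).
  One published cell (physical exercise on SGA, printed as 0.01) is
  numerically implausible as an odds ratio and is replaced by a modest
  protective −0.2. Intercepts are *calibrated*, not asserted: at
  configuration time a deterministic internal draw of 50,000 covariate
  vectors is used to solve each intercept so the implied marginal
  prevalence hits its target, marginalising analytically over the
  realised mediator and (if present) over the latent factor by
  quadrature.
* **Birth measures.** Gestational age is drawn from truncated normals
  consistent with the drawn PB flag (N(34.5, 2.3²) on [26, 37) for
  preterm, N(39.2, 1.3²) on [37, 42] otherwise); birthweight from a
  GA-dependent truncated normal consistent with the drawn LBW flag.
  Postdate-flagged records get GA > 42 so the flag and the rule agree.
  The percentile-based derived SGA therefore lands near 10% by
  construction but is *not* forced to equal the model-drawn SGA — the
  derivation rule and the structural truth are different definitions,
  and both are kept.
* **Missingness** is MCAR by default at configurable per-variable rates
  (an MAR option ties the masking probability to observed income);
  outcome and exposure columns are protected. Masking a derived
  covariate also masks its raw source column so re-derivation cannot
  silently resurrect the cell. The study itself states only that
  multiple imputation was used; rates and mechanism are package
  defaults, exposed in configuration.

What the generator does **not** emulate: spatial structure beyond the
community label (no land-use regression; exposures are drawn, not
predicted from geography), temporal/trimester exposure windows,
measurement error in exposures or outcomes, and informative (MNAR)
missingness. Passing tests therefore demonstrate internal validity of
the estimator pipeline under the emulated data-generating process, not
robustness to those unmodelled features of real cohort data.

## Cohort derivation rules

* PB = gestational age < 37 completed weeks; LBW = birthweight ≤ 2500 g
  (boundary inclusive); postdate exclusion is GA > 42.0 with exactly
  42.0 retained.
* SGA uses the empirical within-sample 10th percentile of birthweight
  inside completed-gestational-week strata (floor of GA), with inclusive
  ≤ comparison and type-7 quantile interpolation — configurable, because
  quantile conventions are a genuine free choice. Strata smaller than
  two infants are pooled with the nearest adjacent weeks, with a
  warning. An alternative reading ("adjusted") takes the 10th percentile
  of residuals from a linear regression of birthweight on GA; the
  stratified rule is the default.
* Exclusions are applied in the narrative order (pregnancy-loss and
  multiplicity reasons, then relocation, then postdate). The final count
  is order-invariant but the flow report is not, so the order is fixed.
  Records with missing GA and no postdate flag are quarantined into
  their own flow row rather than silently dropped.

## Multiple imputation

`impute_chained()` is a compact chained-equations implementation:
predictive-mean matching (Bayesian coefficient draw, five donors) for
continuous variables and logistic draws with coefficient perturbation
for binary ones, visit order by ascending missingness, ten cycles, m =
20 by default. Outcomes are never imputed. Pooling follows Rubin's
rules with Barnard–Rubin degrees of freedom. The imputation model
includes outcomes and exposures as predictors, as proper imputation
requires.

## Numerical choices

* Probabilities are clamped to [1e-12, 1 − 1e-12] and linear predictors
  to [−30, 30] inside likelihoods; the link maps saturate outside the
  representable band.
* GLM convergence: |Δ log-likelihood| < 1e-10 and score infinity-norm
  < 1e-8, at most 100 iterations, step-halving guarantees monotone
  likelihood. Starting values: zero slopes, intercept at
  $g(\bar y)$ with the mean clipped to $[1/(n+1), n/(n+1)]$.
* Separation is detected as a clamped fitted probability that *agrees*
  with its outcome at convergence (the clamp is then the only thing that
  stopped the optimiser, i.e. the MLE is at infinity), or a linear
  predictor beyond ±30, or a diverging coefficient norm; it raises an
  error naming the offending predictor. There is no penalised fallback.
* Model-based covariance is the inverse observed information, falling
  back to the expected (Fisher) information if the observed one is not
  positive-definite at the optimum.
* BIC uses n = number of records, not records × equations.
* Delta-method gradients are analytic for path products and sums;
  a central finite-difference fallback (step 1e-6 scaled) covers
  arbitrary smooth expressions.

## Problem sizes in the test suite

The suite calibrates the estimator with a 200-replicate recovery study
at n = 5000 under the cloglog truth (per-coefficient bias below 0.02,
aggregate 95% Wald coverage within [92%, 98%]); the recovery design
centres continuous covariates and uses moderate binary prevalences so
that every coefficient — intercepts included — carries a per-replicate
standard error small enough for a 200-replicate study to detect biases
of that size. Bootstrap coverage of the true indirect effect uses 200
cohorts of 500 records with 240 resamples each; the delta-vs-bootstrap
agreement uses one cohort of 2000 with 2000 resamples. Copula and
marginal calibration checks run at 100,000 draws. Latent-model checks
use single fits at n = 2000–4000, assessed on the likelihood-ratio
scale as discussed above. These sizes were chosen so each guarantee is
tested at the scale where its Monte-Carlo error is decisively smaller
than the tolerance it asserts.

## Known limitations

* Coefficient-product mediation is not a counterfactual decomposition
  under nonlinear links; no exposure–mediator interactions in v1.
* No non-recursive (feedback) systems, no count/multinomial families,
  no survey weights.
* Near-zero latent variances and the mediator-versus-factor ridge are
  weakly identified with three binary indicators (see above); latent
  results should be read through their likelihood-ratio evidence, not
  their point estimates.
* Separation errors out loudly by design; there is no Firth-type
  penalised rescue.
* This package ships as a programmatic interface (functions plus the
  acceptance script); orchestration is `run_pipeline()` rather than a
  shell executable, which is the natural surface for an analysis
  package used from R.
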