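---
title: "Morbidity-adjusted regional comparison of health-care outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morbidity-adjusted regional comparison of health-care outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(regionvar)
```

## The problem

Regions differ in health-care spending, hospital use and treatment quality
for two very different reasons: their populations differ in morbidity, and
the care delivered to comparable patients differs. Any fair regional
comparison has to separate the two. `regionvar` implements a two-step
strategy built around a categorical population classification ("PopGroups"):
mutually exclusive person categories that combine demographic and diagnostic
attributes, delivered as input labels on a person-level claims panel.

1. **Indirect standardization.** Per region, an observed-to-expected (O/E)
   ratio whose expected value is what the region would have experienced if
   each of its strata had the national per-person outcome level.
2. **Multilevel regression.** A two-level random-intercept model that
   attributes outcome variation to the patient level (the PopGroup) and to
   the regional level, yielding an intraclass correlation, per-region
   effects, and — with regional covariates — candidate explanations for the
   regional component.

## Observed-to-expected ratios

For region $j$ the standardized outcome ratio is
$\mathrm{SOR}_j = Y_{j;O} / Y_{j;E}$ with
$Y_{j;E} = \sum_{s} N_{j;s}\, \bar Y_{r;s}$, where $s$ runs over strata,
$N_{j;s}$ is the region's person count in stratum $s$ and $\bar Y_{r;s}$
the national mean outcome per person in that stratum. Stratifying by
age-sex cells gives the ASOR (`standardize_regions(..., flavor =
"age_sex")`, 5-year bands by two sexes by default — the band width is a
package choice and configurable); stratifying by PopGroup gives the PGSOR.
The reference population is always the pooled panel itself, which buys a
useful algebraic identity: summed over all regions, expected equals
observed exactly, so the national pooled O/E is 1 and every ratio reads as
"relative to the national average". A ratio of 1.47 means 47% more of the
outcome than the region's case mix predicts.

Two numerical conventions matter. Ratios are displayed at 2 decimals
(`format_ratio()`) but kept at full precision internally, so a region with
74 observed and 50 expected events prints 1.48 — a published table that
prints a slightly different second decimal has typically rounded the
expected count before dividing, and we deliberately do not reproduce that.
A region whose expected value is 0 (tiny region, rare outcome) gets a
missing ratio and a warning rather than an error, and ranking functions
exclude and report such regions.

## The multilevel model

With persons $i$ nested in regions $j$, the random-intercept model is
$$y_{ij} = \gamma_{00} + u_{0j} + \gamma_{01}\,\mathrm{PG}_{ij} + \varepsilon_{ij},
\qquad u_{0j} \sim N(0, \tau^2),\ \varepsilon_{ij} \sim N(0, \sigma^2),$$
where $\mathrm{PG}_{ij}$ enters as a set of dummies whose reference is the
most populated group (ties broken by the lexicographically smallest group
id). Cost and bed-day outcomes are strongly right-skewed, so they are
modelled on the natural-log scale; binary outcomes use the binomial family
with the logit link, and predicted probabilities come from the logistic
transform $\theta = e^{\eta}/(1 + e^{\eta})$. Regional covariates $Z_j$
(average population age, density, GP and bed supply, urbanization,
deprivation) extend the model to
$y_{ij} = \gamma_{00} + u_{0j} + \gamma_{01}\mathrm{PG}_{ij} +
(\gamma_{10} + u_{1j}) Z_j + \varepsilon_{ij}$, with the random slope
$u_{1j}$ optional per covariate.

Estimation is delegated to `lme4`: REML for the log-linear models, adaptive
Gauss-Hermite quadrature (7 nodes by default) rather than penalized
quasi-likelihood for the logistic models, because the accuracy of the
variance components is the whole point and because an independent
non-adaptive quadrature oracle (`marginal_loglik_oracle()`, 101 nodes,
log-sum-exp accumulation) can then check the fitted likelihood directly.
Vector-valued random effects (random slopes) restrict `glmer` to the
Laplace approximation; the package downgrades `nAGQ` automatically in that
case. The logistic optimizer runs with `nloptwrap` and without the final
derivative check — on panels with tens of fixed effects this cuts the fit
time several-fold without moving the estimates at the tolerances we test.

The intraclass correlation is
$\mathrm{ICC} = \tau^2 / (\tau^2 + \sigma^2)$, computed from the
*unconditional means* model (no predictors), since it is meant to describe
the raw share of variation sitting between regions. For binary outcomes
there is no level-1 residual on the latent scale, and the standard logistic
convention $\sigma^2 = \pi^2/3 \approx 3.29$ is substituted.

Explained variation is reported as adjusted $R^2$ on the log scale from the
fixed-effect prediction only (the conditional fixed-plus-random $R^2$ is
returned separately, not as the headline number), and as Nagelkerke's
$R^2$ for binary fits. Nagelkerke's statistic is computed from *marginal*
likelihoods of the fitted and the unconditional-means models; a conditional
version would mix in the estimated random effects and is not what a
likelihood-ratio-based pseudo-$R^2$ means.

## Regional performance measures

Per-region effects are empirical-Bayes (shrunken) predictions of $u_{0j}$:
region estimates from finite samples are noisy, and shrinkage toward zero
is the standard answer in provider profiling. Binary fits are summarized as
odds ratios $e^{\hat u_{0j}}$ with Wald limits
$e^{\hat u_{0j} \pm z\,\mathrm{SE}}$ on the prediction scale — the package
makes no stronger claim about interval coverage than that. Continuous fits
are summarized as regression-based PopGroup-adjusted O/E ratios: the
region's predicted total including $\hat u_{0j}$, divided by the prediction
with the intercept zeroed, both back-transformed with the log-normal
smearing factor $e^{\sigma^2/2}$. The smearing factor (and, when a log
offset was used, its back-correction) cancels in the ratio; it matters only
if absolute levels are extracted. On the log scale the ratio is exactly
$e^{\hat u_{0j}}$, which is also how the identity tests pin it down.

The small-group rule precedes every regression: groups holding less than 1%
of the panel (inclusive at the boundary — exactly 1% is retained) are
replaced by their macro group. The rule is applied to regression inputs by
default and to standardization only on request, because the fragility it
addresses — empty region-by-group cells — is a regression problem, not a
standardization problem.

## What the synthetic generator emulates

Real sickness-fund claims are access-restricted, so the package ships a
generator whose defaults mirror the study conditions the framework targets:
96 regions, a few hundred PopGroups with Zipf-distributed shares (exponent
1.1: few large, many tiny groups), 10 macro groups, and the two-level
outcome model above with log-normal costs and Bernoulli hospitalization.
Choices a user should know about:

* **Severity gradient.** Each group has one latent standard-normal value
  that scales both outcomes' effects (`effect_sd` of 0.8 on the log-cost
  scale and 0.7 on the logit scale — spreads that give cost ratios and odds
  ratios across groups of the magnitude case-mix systems are built to
  capture) and maps affinely onto the published severity score range (-0.4
  to 13.1). The real score construction is proprietary to the grouping
  algorithm and out of scope; the affine map preserves the only property
  the framework uses, monotonicity in the outcome effect.
* **Compositional confounding.** Regional group mixes are
  Dirichlet-perturbed national shares with concentration
  `composition_shift` x shares. The default of 50 produces visibly
  different regional case mixes without emptying strata; `Inf` switches
  confounding off, which is how the cross-method concordance tests isolate
  method agreement from case-mix effects.
* **Baselines.** Default grand means are 6.0 log-EUR (a reference-group
  median around 400 EUR/year, low because the reference is the most
  populated — typically healthy — group) and -2.2 logits (a ~10% national
  hospitalization rate). Regional SDs default to `tau` = 0.5 (log scale)
  and `sqrt(0.3)` (logit scale), i.e. ICCs of 0.2 and 0.08 — inside the
  0.05-0.20 band typical of cross-sectional multilevel applications.
* **Shared regional draw.** Both outcomes share one standard-normal
  regional deviate by default (scaled by their own `tau`), so
  efficiency-vs-quality cross-comparisons have something to find;
  independence is a flag away.
* **Determinism.** All randomness flows from one master seed through fixed
  substreams (catalog, population, outcomes, covariates); identical spec
  and seed give bit-identical panels.

The generator emulates exactly the structure the models assume. Passing
recovery tests therefore demonstrates correctness of the estimation
machinery, not robustness to real claims data, which bring coding-practice
artifacts, informative enrollment, within-person outcome dependence beyond
the shared intercept, and regional covariates correlated with case mix.
The generator draws covariates independently of the regional intercepts,
so covariate-adjusted fits on synthetic data test mechanics, not
confounding control.

## Problem sizes and tolerances in the test suite

Recovery tests run at J = 96 regions and n = 50,000 persons with 40
PopGroups, 20 replicates for the replicate-mean checks — large enough that
mean variance-component errors sit well inside the 15% band the suite
asserts, small enough to keep a full run in minutes. The quadrature oracle
is checked at J = 10, n = 500 against a 15-node adaptive fit (agreement
within 1e-4 of log-likelihood; observed discrepancies are below 1e-5). The
balanced-design identity (REML equals one-way ANOVA method-of-moments
components) is asserted to 1e-6. Conservation of pooled O/E is asserted to
1e-9 relative, which is three orders of magnitude above the accumulation
error actually observed. Near-boundary variance estimates (true
$\tau^2_1 = 0$) are asserted to be far below what a genuinely heterogeneous
slope would produce rather than numerically zero, since REML boundary
estimates at ~100 regions have sampling noise of order 0.01.

## Known limitations

* Three-level structures (patients in practices in regions), spatial
  correlation between neighbouring regions and crossed random effects are
  out of scope.
* O/E ratios are point estimates; the package attaches no confidence
  intervals to them (the regression route provides intervals via the
  random-effect predictions instead), and no multiple-testing adjustment
  is applied across regions.
* The log transform with offset `log(y + 1)` makes the continuous model's
  grand mean depend on the currency unit for panels with many zeros;
  analyses comparing absolute levels should fit with `log_offset = 0` on
  strictly positive outcomes or state the offset.
* Within-person dependence between outcomes is modelled only through the
  shared regional intercept; given the linear predictors, outcomes are
  independent.
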