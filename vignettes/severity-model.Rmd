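---
title: "A latent-variable global severity score for CDKL5 deficiency disorder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A latent-variable global severity score for CDKL5 deficiency disorder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cddseverity)
```

## The problem

CDKL5 deficiency disorder (CDD) is a severe developmental and epileptic
encephalopathy whose burden spans motor function, vision, communication,
seizures, alertness, feeding and sleep. Clinical trials need a single
severity endpoint, but each clinical outcome assessment (COA) captures only
one slice of the phenotype, and most standardized instruments floor out in
severely affected children. The approach implemented here treats severity as
a latent construct: observed COA scores are imperfect reflections of
underlying severity factors, and a per-subject global severity score is the
best estimate of the latent construct given whatever scores that subject has.

## The model

Nine observed scores enter the model, in three reflective blocks:

| Latent | Indicators | Instrument |
|---|---|---|
| Communication | communication domain; CSBS-DP ITC total | clinician CCSA; caregiver questionnaire |
| Comorbidities | insomnia; daytime sleepiness; seizures; alertness | SDSC; caregiver CCSA |
| Global severity | motor; vision; feeding | clinician CCSA; caregiver CCSA |

Communication and Comorbidities are exogenous and covary freely; Global is
endogenous, regressed on both, and directly measured by motor, vision and
feeding. With loading matrix $\Lambda$, structural coefficients $B$, latent
(co)variances $\Psi$, residual variances $\Theta$ and intercepts $\nu$:

$$\mu(\theta) = \nu, \qquad
  \Sigma(\theta) = \Lambda (I-B)^{-1} \Psi (I-B)^{-T} \Lambda^{T} + \Theta.$$

Assumptions worth stating plainly: indicators are conditionally independent
given their latent factor (diagonal $\Theta$); relations are linear; scores
are treated as continuous multivariate normal. Bounded, skewed instrument
scales violate normality at the margins — this is the standard compromise of
linear SEM on clinical scale scores, and the simulation studies below
quantify how little it matters for recovery under realistic conditions.

### Identification and the direction of the Global arrows

Each latent is scale-identified by fixing its first indicator's loading to
one (motor for Global, the clinician communication domain for Communication,
insomnia for Comorbidities), leaving latent variances free. Unit-loading
identification keeps loadings and factor scores on the indicators' metric,
so the derived weights are stable under rescaling of the cohort.

The direction of the arrows around Global admits two readings: the default
here makes the two domain factors causes of Global
(Communication → Global ← Comorbidities) with Global reflected by
motor/vision/feeding, matching the exogenous/endogenous labelling of the
constructs. A fully second-order alternative (Global → Communication,
Global → Comorbidities) is equally expressible; rather than hard-coding one
reading, both are shipped as model configs
(`inst/extdata/cdd_model.yaml`, `inst/extdata/cdd_model_second_order.yaml`)
and `parse_model_config()` accepts either. Nothing downstream (FIML, factor
scores, weights) depends on which structure is chosen beyond the implied
covariance it generates. The default model has $q = 30$ free parameters
against $9 \cdot 12 / 2 = 54$ first and second moments, hence 24 degrees of
freedom.

## Estimation: FIML over missingness patterns

Subjects with at least two of the nine scores are retained
(`filter_inclusion()`; a variant counting distinct instruments instead of
variables is provided, since "two or more scores" is ambiguous between the
two). The observed-data log-likelihood sums, over subjects, the normal
log-density of the observed subvector under the correspondingly subset
$\mu(\theta), \Sigma(\theta)$. Rows are grouped by missingness pattern and
evaluated from per-pattern sufficient statistics (count, mean, centered
scatter), which is algebraically identical to the per-row sum — a property
the test suite checks to 1e-8 on random masks — while making the cost per
optimizer step independent of cohort size.

Numerical choices:

* **Parameterization.** Variances are log-transformed; the exogenous latent
  covariance is $\tanh(z)\sqrt{\psi_1\psi_2}$, keeping $\Psi$ admissible for
  any unconstrained vector. A non-positive-definite pattern submatrix is an
  inadmissible-parameter signal (`-Inf` likelihood), not an error.
* **Start values** (documented, fixed): free loadings 1, structural
  coefficients 0.5, zero latent covariance, latent and residual variances at
  half the pooled sample variance, intercepts at observed means.
* **Convergence.** Quasi-Newton (`nlminb`) with relative objective tolerance
  1e-10, step tolerance 1e-8, 500-iteration cap; a central-difference
  gradient check at the optimum is recorded (`gradient_norm`, relative to
  1 + |loglik|) and a fit failing it is flagged, never silently returned.
* **Reference models.** The saturated model (unstructured moments) is fitted
  by EM over the same missingness patterns; the baseline model (free means
  and variances, zero covariances) separates per variable and is closed
  form. This keeps $\chi^2 = 2(\ell_{sat}-\ell_{model})$ and the incremental
  indices internally consistent under missingness.
* **Fit indices.** RMSEA uses the $(n-1)$ denominator by default (software
  differs on $n$ vs $n-1$; the difference is under 0.3% at $n \approx 200$,
  and both are available via `fit_options(rmsea_n=)`). TLI is reported
  uncapped and is undefined (NA with warning) when the baseline ratio is
  ≤ 1. A just-identified model (df = 0) reports RMSEA 0 by convention.
* **No standard errors.** Only point estimates, fit indices and scores are
  produced; interval estimation for $\theta$ is out of scope.

## Scores, harmonization, weights

Factor scores are regression-method conditional expectations
$E[\eta \mid y_{obs}] = \Psi_\eta \Lambda_{obs}^T \Sigma_{obs,obs}^{-1}
(y_{obs} - \mu_{obs})$, generalized to any missingness pattern; a subject
with no observed scores gets NA. Global scores are standardized to mean 0 /
SD 1 over the fitted cohort, higher = more severe.

Before weighting, the nine scores are harmonized to a common 0–100
severity-oriented metric: linear map to 0–100, then reversal of
higher-is-better instruments. The default orientation follows the
instruments' scoring card as published with the cohort description: the CCSA
domains and the sleep questionnaire score higher = better functioning (so
they are reversed), while the CSBS-DP ITC and the quality-of-life total are
recorded higher = greater severity (so they pass through). Because the CSBS
convention in particular is frequently quoted in the opposite direction,
orientation is a per-variable argument everywhere, never hard-coded.

Weights are the OLS slopes of the standardized global factor score on the
nine harmonized components over complete cases, rescaled to sum to one
(intercept discarded). On complete data the factor score is exactly linear
in the indicators, so the regression has $R^2 = 1$ and the weighted average
reproduces the factor score up to a positive affine map — the test suite
asserts correlation 1 to 1e-8. Negative slopes are kept with a warning
(truncating them would break that reconstruction); the shipped published
weights store the printed values, whose sum is 0.999 from rounding, and
renormalize by that sum at load so the unit-sum invariant holds exactly
without inventing digits. Scoring a profile with missing components refuses
by default and names what is absent; an opt-in policy renormalizes the
remaining weights, which is an extrapolation beyond the published rule and
is labelled as such in the output.

## Validation statistics

* **Pearson correlations** with external correlates (EEG alpha/delta and
  theta/delta band-power ratios, quality-of-life total, caregiver behavior
  domain) use pairwise-complete observations — each correlate has its own n
  — with Fisher-z 95% intervals. Both EEG ratios are always reported
  separately. No multiplicity adjustment is applied, matching how such
  convergent-validity panels are conventionally reported.
* **Age-group comparison** is a Welch two-sample t-test by default (robust
  to unequal variances), with the pooled-variance Student test as an option.
* **Test–retest reliability** is ICC(A,1): two-way mixed-effects,
  absolute-agreement, single measurement, computed from the ANOVA mean
  squares, with the McGraw & Wong (1996) F-based confidence interval; a
  one-way random-effects form is available. Bands: good 0.75–0.9, excellent
  above 0.9. The form used is printed in every result row.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` draws standard-normal latents with the configured
structural coefficients (the Global disturbance variance is set so
Var(Global) = 1 exactly), builds each score as loading × latent + Gaussian
noise, then maps it affinely onto its instrument scale and clips to the
declared range. Defaults reproduce the published cohort's shape: n = 206,
score means from the cohort description, instrument-block missingness with
exact realized counts (caregiver 4%, CSBS 20%, clinician 28%, QoL 30%, sleep
39%, EEG 45/206 assessed), a retest subgroup of 18/206 about four weeks
later, 51.5% under 7 years and 82% female with demographics independent of
severity (so age-group comparisons are null by design), and external
correlates generated linearly in Global at targets 0.61 (alpha/delta), 0.68
(QoL) and −0.21 (behavior).

Choices the data do not dictate, made once and documented:

* **Scale SDs.** The published means/SDs imply substantial boundary mass
  under a normal model (e.g. feeding: mean 36.5, SD 33.5 on 0–100). Default
  generating SDs are the published SDs shrunk so that mean ± 2.81 SD stays
  in range, keeping boundary clipping below ~1% (logged per cohort as
  `clip_fraction`). Heavy truncation would distort the linear SEM the
  fitting stage assumes; the cost is that generated scores are mildly less
  dispersed than the real ones.
* **Generating loadings and residual SDs** are set so indicator–Global
  correlations are strong for motor and the communication measures and weak
  for the sleep domains, qualitatively matching the published weight
  ordering. They are config, not constants.
* **Missingness mechanism.** Instrument-block MCAR by default — all domains
  of a questionnaire missing together, which is how per-instrument
  missingness is reported. An MAR option tilts selection toward severe
  subjects through a logistic weight while keeping the marginal rate exact,
  for robustness experiments. The true mechanism in the study is unknown.
* **Retest model.** A retest row equals the baseline score plus fresh
  occasion noise, clipped to range — the baseline observation is treated as
  the subject's stable four-week state. This makes the noiseless limit
  reproduce baseline exactly (ICC = 1 exactly) and gives the closed form
  population ICC $v/(v + s^2/2)$ for baseline variance $v$ and occasion-noise
  SD $s$, inverted by `retest_sd_for_icc()`; the default noise targets
  ICC 0.9 per score, in the range reported for the real instruments. The
  alternative (redrawing measurement noise at both occasions around a shared
  true score) is statistically cleaner but cannot reproduce baseline in the
  noiseless limit.
* **External-correlate anchoring.** Reported correlations are measured
  against an *estimated* severity score, which attenuates them relative to
  the latent (the weighted composite correlates about 0.96 with latent
  Global under defaults). Targets can therefore anchor on the latent
  (default) or on the harmonized weighted composite under a given weight
  set, with the generating slope corrected using the closed-form
  `implied_composite_cor()`.

What the generator does **not** emulate: the skew of real instrument
distributions (scores are clipped Gaussians; real distributions of, e.g.,
feeding scores pile up near the floor), item-level structure of the
questionnaires, age trajectories (the developmental plateau around age 7 is
not modelled — age is decorative), or any misspecification of the SEM
itself. Passing tests therefore demonstrate that the machinery is correct
and well-calibrated *when the model is true*, not that the model is true of
CDD.

## Reproducibility and problem sizes

All randomness flows from explicit seeds: `generate_cohort()` uses
`config$seed`, the retest stage uses `config$seed + 500009`, and both
restore the caller's RNG state. Identical config and seed give byte-identical
tables, and the pipeline is deterministic given its input, so repeated runs
write identical score files.

The simulation studies in the test suite and acceptance script use sizes
chosen to make Monte-Carlo error small relative to the tolerance being
checked while keeping a full run in minutes on one core: moment recovery at
n = 10,000 against the generator's closed-form correlation matrix (entrywise
0.03); implied-moment verification against a brute-force simulation of 10⁶
draws (0.01); parameter recovery and fit-index calibration over 50
replicates at n = 1,000, complete and under 30% instrument-block MCAR;
reliability recovery at 2,000 retest pairs (±0.02 around the designed 0.9);
external-correlation recovery at n = 20,000 (±0.02 around 0.61); interval
coverage for the Fisher CI over 1,000 draws at n = 45.

## Known limitations

* Continuous-normal treatment of bounded ordinal-ish scale scores; no
  robust or categorical estimators.
* No standard errors or bootstrap intervals for model parameters or weights.
* The weighted-average scorer assumes the published harmonization ranges;
  applying it to instruments scored differently requires re-deriving
  weights.
* Single-group, cross-sectional model: no measurement-invariance testing
  across age groups and no longitudinal growth structure, although the
  scaffolding (config-driven model structures) would admit them.
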