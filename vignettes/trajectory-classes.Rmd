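---
title: "Joint trajectory classes of childhood constipation and soiling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint trajectory classes of childhood constipation and soiling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(llca)
library(dplyr)
```

## The problem

Constipation and soiling (faecal incontinence) are common in primary-school
children, and they are related: soiling is often attributed to overflow from
chronic constipation, but a fraction of children soil without any
constipation. Repeated maternal reports — five waves of a binary soiling
indicator between roughly 4½ and 9½ years, six waves of a binary
constipation indicator between roughly 4¾ and 10¾ years — allow both
problems to be described as developmental trajectories rather than
point-prevalence snapshots. This package implements the full modelling chain
for that design:

1. **Single-process longitudinal latent class analysis (LLCA)** — a finite
   mixture in which each latent class \(c\) has its own per-wave symptom
   probability \(\rho_{ct}\) and weight \(\pi_c\), with items independent
   given class (local independence) and missing items skipped
   (missing-at-random / full-information likelihood).
2. **A parallel-process model** — two linked 4-class latent variables, one
   per symptom process; given a class pair \((a, b)\), soiling items depend
   only on \(a\) and constipation items only on \(b\), so all dependence
   between the processes is carried by the \(4 \times 4\) joint weight
   matrix \(\pi_{ab}\), estimated on the full 15-parameter simplex.
3. **Collapse to four composite clinical groups** — normative (both classes
   normative), constipation alone, soiling alone, constipation with soiling;
   a deterministic map of the 16 cells (1 + 3 + 3 + 9).
4. **Bias-adjusted three-step regression** — modal assignment to a composite
   group is imperfect, and regressing modal labels on risk factors
   attenuates associations. The three-step approach quantifies the
   assignment error with the matrix
   \(D_{tm} = \Pr(\text{assigned } m \mid \text{true } t)\) and maximises
   the misclassified-outcome likelihood
   \(\sum_i \log \sum_t P(t \mid x_i; \gamma)\, D_{t, m_i}\),
   a multinomial logit on the *true* class with normative reference.

## Estimation choices

**EM with multiple random starts.** The observed-data log-likelihood is
maximised by EM: the E-step computes posterior class probabilities over
observed items only; the M-step updates \(\pi\) as the mean posterior and
\(\rho_{ct}\) as the posterior-weighted mean of observed \(y_t\). Defaults:
50 random starts for single-process fits (uniform-Dirichlet weights,
Uniform(0.05, 0.95) item probabilities), relative log-likelihood tolerance
1e-8, at most 5000 iterations. All starts first run a short phase (30
iterations) and only the best few are polished to convergence — the standard
multi-start schedule for mixture models. Children are collapsed onto unique
response patterns, so the E-step cost is bounded by the number of distinct
patterns (at most \(3^T\)), not the sample size. \(\rho\) is clamped to
\([10^{-6}, 1 - 10^{-6}]\) so sparse cells cannot produce degenerate
\(-\infty\) likelihoods; `llca_loglik()` itself tolerates exact 0/1
probabilities and returns \(-\infty\) contributions where they are
contradicted.

**The parallel model** is initialised from a warm start — the two
single-process fits with product-of-marginals joint weights — plus random
starts, and all measurement parameters are re-estimated jointly.
Because EM ascends from the warm start, the parallel log-likelihood is never
below the sum of the two independent fits, which is also a property test.

**Label switching** is resolved by `canonical_order()`: classes are sorted
by mean item probability (ascending, so the lowest-burden class is the
normative one), ties broken by the first wave at which the probability
exceeds 0.5 (early onset before late onset), then by weight. In the parallel
model the rule is applied to each process's implied marginal model.

**Class enumeration.** The headline pipeline fixes four classes per process.
`enumerate_classes()` reports log-likelihood, BIC
(\(-2\ell + k \log n\)), AIC, entropy-based classification quality and the
smallest class share across a range of class counts; BIC is the default
selection criterion, and on well-separated synthetic 4-class data it selects
four classes in essentially every replicate.

**Three-step details.** \(D\) is computed on the collapsed 4-group
classification (the scale on which the regressions are reported), is treated
as fixed in step 3, and standard errors come from the observed information
of the step-3 likelihood — step-1 uncertainty in \(D\) is not propagated,
a known limitation of the approach. The step-3 likelihood, unlike ordinary
multinomial logit, is not concave: the optimiser therefore starts from a
quick naive modal-label fit and from a start whose intercepts invert \(D\)
on the marginal label frequencies, runs BFGS with the analytic gradient, and
Newton-polishes until the gradient max-norm is below 1e-8. With \(D = I\)
the estimator reproduces ordinary multinomial regression to optimiser
precision (tested against `nnet::multinom`). Identical covariate rows with
the same label are aggregated with counts, so categorical designs cost a
handful of weighted rows. Wald 95% intervals are
\(\exp(\gamma \pm 1.96\,\mathrm{SE})\); the omnibus test for a factor is the
Wald chi-square of all its coefficients across the three non-reference
groups, with df = (levels − 1) × 3 (3 for a continuous factor). Apparent
separation (|log-odds| > 10) is flagged. Missing covariate values are
dropped listwise per model.

## What the synthetic cohort generator emulates

No individual-level data accompany the published analysis, so the package
ships a generator whose defaults encode the published study conditions:

* **Joint class structure**: the published 4×4 joint distribution (the one
  censored "<0.1" cell carried as 0 — the printed cells then sum to exactly
  100, so no renormalisation is needed). Collapsing it yields composite
  shares 74.5 / 13.2 / 7.5 / 4.8.
* **Trajectory shapes**: per-wave symptom probabilities chosen once to match
  the published qualitative shapes — normative low throughout (≤ 0.05),
  early-onset high then resolving (high until about age 6), late-onset
  emerging after about age 6, persistent ≥ 0.7 throughout. The values also
  make the class-mean ordering normative < early < late < persistent, so
  the canonical ordering reproduces the published row/column order, and they
  imply weight-averaged marginal prevalences in the published 5–15% band
  (slightly below the printed first-wave constipation prevalence of 14.5%;
  only the qualitative shape is claimed).
* **Covariates**: the published risk-factor set with its printed level
  prevalences. Effects on class membership act on the four composite groups
  (the level at which the published regressions operate) through a
  multinomial logit whose intercepts are calibrated at the reference
  covariate pattern; within a composite group the joint cell is drawn with
  the base joint weights. Defaults set all effects to zero so the marginal
  composite distribution reproduces the joint table exactly;
  `alspac_covariate_specs("published")` switches on the published odds ratios
  (which then tilt the marginal shares — the published joint table is
  unconditional, the regressions conditional).
* **Missingness**: each assessment is answered with probability 0.975, and a
  geometric dropout hazard of 0.05 per age-ordered assessment occasion
  imposes monotone attrition. These two numbers were chosen once so the
  nested-sample gradient (≥1 non-missing wave on both processes, ≥3 waves on
  both, complete case) roughly matches the published 10450 / 8435 / 4931
  sizes; no exact mechanism is claimed. The mechanism is MCAR — stronger
  than the MAR assumption the estimator needs — and independent of class.

What the generator does **not** emulate: the pre-dichotomisation
questionnaire response options, informative (MNAR) missingness, sibling or
twin clustering, within-wave age variation (wave ages are labels only), and
any covariate–covariate correlation. Passing recovery tests on this
generator therefore shows the estimators are correct under the stated model,
not that the model is correct for real cohort data.

## Numerical and design notes

* Degenerate inputs: children with no observed waves are excluded (with a
  warning) before fitting; a child impossible under every class raises an
  error naming the child; a composite group with zero posterior mass makes
  `error_matrix()` fail with the group's name; a singular \(D\) is rejected.
* Modal ties break toward the less severe group (fixed order normative,
  constipation alone, soiling alone, constipation with soiling) —
  deterministic and conservative.
* Display rounding follows the published tables (one decimal for class
  percentages, integer percentages for the soiler split); all arithmetic is
  done unrounded, and an estimated joint cell in (0, 0.05)% is rendered
  "<0.1" in the display table.
* Wave indices are 0-based internally; age labels are metadata.
* Reproducibility: one master seed per fit; per-start seeds are derived from
  it, and the pipeline is bit-reproducible given its config.

## Problem sizes used in the shipped checks

The recovery experiments in the test suite and the acceptance script use the
published analytic sample sizes — n = 8435 for the parallel model and the
regressions, n = 8979 for the constipation-only model — with 20–25
replicates per experiment and fully observed panels (the published n are
post-filter analytic sizes; missing-data handling is exercised by its own
invariance tests, such as the all-missing-wave refit identity). The type-I
error of the omnibus Wald test is checked with 1000 null replicates at
n = 8435; at much smaller n the chi-square approximation is visibly
conservative for the rare classes.

## A worked run

```{r example, eval = FALSE}
cfg <- cohort_config(n_children = 8435, seed = 1)
cohort <- generate_cohort(cfg)
panel <- apply_missingness(cohort$panel, cfg) |>
  apply_inclusion_filter(min_waves = 3, process = "both")

fit <- fit_parallel(panel, n_starts = 5, seed = 1)
joint_class_table(fit, censor_small = TRUE)

composite <- collapse_posterior(fit)
100 * composite_proportions(fit$joint_weights)
soiler_split(composite_proportions(fit$joint_weights))

reg <- fit_threestep(cohort$covariates, ~sex, composite)
tidy(reg)
omnibus_test(reg, "sex")
```

The same chain, with per-stage files and a text report, is available as
`run_pipeline(pipeline_config(...))` followed by `write_results()`.

## Known limitations

* Standard errors of the three-step regression ignore the sampling
  variability of the fitted \(D\) and of the step-1 class model.
* The weighting-based (as opposed to maximum-likelihood) three-step variant
  is not implemented.
* The generator draws covariates independently of each other, so
  multivariable adjustment on synthetic data exercises the code path but not
  realistic confounding strength.
* With four classes per process fixed, poorly separated real data could
  still prefer other class counts; `enumerate_classes()` is the diagnostic.
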