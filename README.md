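# llca

Longitudinal and parallel-process latent class models for childhood
constipation and soiling.

## What this is for

Epidemiologists studying childhood bowel problems often have repeated binary
symptom reports — here, maternal reports of soiling at five waves (ages
~4½–9½ y) and constipation at six waves (ages ~4¾–10¾ y) — and want to know
(i) what developmental trajectories the two symptoms follow, (ii) how often
they co-occur, and (iii) which early-childhood factors predict each pattern.
This package implements that analysis chain end to end:

* **LLCA** (`llca_fit`): a finite mixture for repeated binary indicators.
  Class *c* has weight *π<sub>c</sub>* and per-wave symptom probability
  *ρ<sub>ct</sub>*; items are independent given class and missing items are
  skipped (MAR). Estimated by EM with multiple random starts; classes are
  enumerable by BIC (`enumerate_classes`) and canonically ordered
  (`canonical_order`) so "normative", "early", "late", "persistent" are
  reproducible labels.
* **Parallel-process model** (`fit_parallel`): two linked 4-class latent
  variables, one per symptom, with the dependence carried entirely by a
  4×4 joint weight matrix *π<sub>ab</sub>* (15 free parameters).
* **Collapse** (`collapse_posterior`, `composite_proportions`): the 16 class
  pairs map deterministically onto four clinical groups — normative,
  constipation alone, soiling alone, constipation with soiling.
* **Bias-adjusted three-step regression** (`fit_threestep`): multinomial
  logistic regression of composite class on risk factors that corrects for
  modal-assignment error using the classification-error matrix
  *D<sub>tm</sub>* = P(assigned *m* | true *t*), maximising
  Σ<sub>i</sub> log Σ<sub>t</sub> P(t|x<sub>i</sub>;γ) D<sub>t,m<sub>i</sub></sub>.
  Reports ORs, Wald 95% CIs and omnibus Wald p-values.
* **Synthetic cohort generator** (`cohort_config`, `generate_cohort`,
  `apply_missingness`, `apply_inclusion_filter`): cohorts with known latent
  structure whose defaults are calibrated to the published joint class
  distribution, trajectory shapes, covariate prevalences/odds ratios and
  attrition, so every estimator can be validated against ground truth.

Everything is tibble-in/tibble-out with `tidy()`/`glance()` methods and
`autoplot()` displays (trajectory profiles, joint-table heatmap, OR forest
plot), plus a file-based pipeline (`run_pipeline`, `write_results`).

## Worked example

```r
library(llca)

cfg    <- cohort_config(n_children = 8435, seed = 1)  # calibrated defaults
cohort <- generate_cohort(cfg)
panel  <- apply_missingness(cohort$panel, cfg) |>
  apply_inclusion_filter(min_waves = 3, process = "both")
dplyr::n_distinct(panel$child_id)
#> [1] 6119

fit <- fit_parallel(panel, seed = 1)
round(joint_class_table(fit), 1)
#>            normative delayed relapse persistent total
#> normative       74.9     1.6     4.1        0.6  81.2
#> early            6.5     0.0     1.0        0.3   7.8
#> late             6.3     0.8     0.5        0.1   7.8
#> persistent       1.6     0.3     0.7        0.6   3.2
#> total           89.4     2.6     6.3        1.7 100.0

shares <- 100 * composite_proportions(fit$joint_weights)
round(shares, 1)
#>                normative        constipation_alone
#>                     74.9                      14.4
#>            soiling_alone constipation_with_soiling
#>                      6.3                       4.3
soiler_split(shares)     # of the soilers: alone vs with constipation
#>     soiling_alone with_constipation
#>                59                41
any_constipation_prevalence(shares)
#> [1] 18.8

composite <- collapse_posterior(fit)
reg <- fit_threestep(cohort$covariates, ~sex, composite)
omnibus_test(reg, "sex")
#> # A tibble: 1 × 4
#>   term  statistic    df p.value
#>   <chr>     <dbl> <int>   <dbl>
#> 1 sex        1.26     3   0.738
```

The joint table estimates the percentage of children in each (constipation
class, soiling class) trajectory cell. Its collapse says ~75% of children
are free of both problems, ~14% follow a constipation-only trajectory, ~6%
soil without constipation and ~4% have both; among soilers, soiling
*without* constipation is the majority (59/41). The generator's covariate
effects default to zero, so the sex omnibus test is (correctly) null here.
Individual soiling sub-cells are the noisiest quantities — at ~6000
analysed children after attrition the delayed/relapse split is only weakly
identified, while the composite shares are stable. The numbers above are
the verbatim output of the commands shown (seed 1); rerunning reproduces
them bit for bit.

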