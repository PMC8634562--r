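# growthpool

Life-course trajectories — how weight, height or any repeatedly measured
outcome evolves from birth to adulthood — rarely fit inside a single cohort
study. `growthpool` implements a complete workflow for **combining
longitudinal data from heterogeneous cohorts that cover different and
overlapping periods of life** into one trajectory model, for
epidemiologists and biostatisticians who need pooled growth curves with
honest uncertainty:

- **Harmonization & pooling** — configurable raw-to-harmonized category
  mappings with defaults for sex, race/ethnicity, maternal education and
  paternal occupational class; exact unit conversion; a nine-level
  parental education × occupation composite; a pooling audit and a
  complete-covariate discard report.
- **Trajectory bases** — fractional polynomials (degrees 1–2, powers
  −2, −1, 0, 0.5, 1, 2, 3, with log and repeated-power conventions) and
  restricted cubic splines (3–7 knots at Harrell's percentiles).
- **A two-level linear mixed model** (measurements within children),
  written for this problem: exact block-diagonal ML/REML with the fixed
  effects profiled out by GLS, unstructured individual-level random
  effects on the intercept and all trajectory terms, and *complex level-1
  variation* — measurement-level variance that changes with age, either
  segmented by age band or `σ₀² + σ₁²·age²`. Estimation uses a
  log-Cholesky parameterization with analytic gradients and EM warm
  starts (RcppArmadillo).
- **Two-stage model selection** — stage 1 chooses the trajectory family
  over 35 FP and 5 RCS candidates on a cohort-stratified random subsample,
  shortlists the top 2 per family by information criterion, and
  adjudicates by mean squared prediction error on the held-out validation
  children; stage 2 chooses the level-1 covariance structure by REML.
  The summed-likelihood alternative (same model fitted per cohort,
  log-likelihoods added) is provided, including its structural failure for
  splines when cohorts cover different age ranges.
- **Interaction pruning** — covariate-by-trajectory (and
  cohort-by-trajectory) interactions without data support — e.g. a spline
  term whose knot lies beyond a cohort's age window — are detected by
  support counts and a rank sweep and dropped, with a log.
- **Iterative multiple imputation** for sporadically *and systematically*
  missing child-level categorical covariates: each cycle refits the full
  analysis model, computes per-child empirical-Bayes trajectory summaries,
  and redraws missing values from multinomial-logistic imputation models
  whose predictors include those summaries — so imputation respects the
  nonlinear trajectory and its interactions. `M` completed datasets are
  pooled by Rubin's rules.
- **A synthetic five-cohort generator** with known truth (visit schedules,
  jitter, monotone dropout, single-sex and systematically missing
  cohorts), so every stage is testable without access to restricted
  cohort data.

## The model

For child *i* with weight `y_ij` at age `t_ij`:

```
y_ij = x(t_ij)' β + z(t_ij)' b_i + e_ij
b_i ~ N(0, G)            unstructured, intercept + all trajectory terms
e_ij ~ N(0, σ²(t_ij))    segmented by age band, or σ₀² + σ₁² t²
```

`x(t)` contains the trajectory basis, cohort indicators and
cohort-by-trajectory interactions (each cohort keeps its own average
trajectory; cohort is a fixed effect because five cohorts are too few for
a third random level), plus covariates and covariate-by-trajectory
interactions. The marginal likelihood is evaluated exactly per child,
`V_i = Z_i G Z_i' + R_i`, by ML or REML.

## Worked example

```r
library(growthpool)

# a synthetic five-cohort study (2,000 children) with known truth
profs  <- default_cohort_profiles(n_children = c(600, 40, 570, 65, 725))
truth  <- default_truth()
pooled <- generate_multi_cohort(profs, truth, seed = 1)

# two-stage selection on a stratified subsample of 1,500 children
report <- select_trajectory(pooled, selection_config(n_select = 1500,
                                                     seed = 1))
report$winner_label
#> [1] "RCS(5 knots: 0, 0.4106, 3.931, 10.08, 16)"

# final fit and a cohort contrast at age 15; cohort-by-spline
# interactions without support in short-window cohorts are pruned first
spec <- model_spec(report$winner, cohort_as_fixed = TRUE,
                   level1 = report$final_spec$level1)
spec <- prune_unsupported_interactions(spec, pooled)$spec
fit  <- fit_growth_model(pooled, spec, method = "REML")
trajectory_contrast(fit, list(cohort = "PROBIT"), list(cohort = "ALSPAC"),
                    age = 15)
#> difference         se        lwr        upr
#> -1.2352489  0.3313452 -1.8846736 -0.5858242
```

The contrast says children in the PROBIT-like cohort average about
1.2 kg lighter at age 15 than the ALSPAC-like reference, with a 95%
delta-method interval; the generating truth places them 0.93 kg apart,
well inside the interval. With
missing covariates the same call sequence goes through
`prune_unsupported_interactions()`, `mi_analysis()` and Rubin's-rules
pooling; `run_pipeline()` executes the whole chain with persisted
artifacts and a checksum manifest.

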