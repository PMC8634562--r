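---
title: "Modelling life-course growth trajectories from pooled heterogeneous cohorts"
author: "growthpool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling life-course growth trajectories from pooled heterogeneous cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of its statistical methods: the
model and its assumptions, the procedures built around it, the numerical
choices, what the synthetic data generator does and does not emulate, and
the design decisions taken where more than one defensible choice existed.

## The problem

No single cohort study follows people from birth to old age with dense
repeated measurements. A practical alternative pools several cohorts that
cover different, partially overlapping age windows — here, five cohorts of
childhood weight spanning birth to age 20, ranging from a small trial
cohort measured fourteen times before age 5 to a school cohort measured
three times a term between ages 9 and 18. Pooling heterogeneous cohorts
raises four methodological problems that this package addresses jointly:
category harmonization, a trajectory model flexible enough for growth,
model selection that no single cohort could support alone, and covariate
data that are missing *systematically* (never measured in a cohort) as
well as sporadically.

## The analysis model

For child $i$ with weight $y_{ij}$ (kg) at age $t_{ij}$ (years):

$$y_{ij} = x(t_{ij})'\beta + z(t_{ij})'b_i + e_{ij},
  \qquad b_i \sim N(0, G), \qquad e_{ij} \sim N(0, \sigma^2(t_{ij})).$$

* **Fixed effects** $x(t)$: the trajectory basis, cohort indicators with
  cohort-by-trajectory interactions (each cohort has its own average
  trajectory), and child-level covariates with covariate-by-trajectory
  interactions. Cohort enters as a *fixed* classification: with only a
  handful of cohorts a third random level cannot support reliable
  variance estimation, so a two-level model (measurements in children) is
  used.
* **Individual level**: random effects on the intercept and *all*
  trajectory columns, with a fully unstructured covariance $G$ —
  children differ in both starting point and shape.
* **Measurement level ("complex level-1 variation")**: a constant
  residual variance is untenable across a 20-year span (adolescent
  weights are far more variable than birth weights). Two structures are
  provided, both with all pairwise covariances fixed at zero:
  *segmented* — independent measurement-level intercepts per age band,
  default bands $\le 2$ and $> 2$ years — and *age-linear* —
  measurement-level intercept and linear-age effects, giving variance
  $\sigma_0^2 + \sigma_1^2 t^2$.

Estimation maximizes the exact block-diagonal marginal likelihood (the
children are independent), by ML or by REML; REML is the default for
inference because ML variance estimates are biased downward. Missing
*outcome* data are handled by the likelihood itself: under
missing-at-random dropout the fitted model is valid without imputing
outcomes, and the package deliberately never imputes them.

### Numerical implementation

The fixed effects are profiled out by generalized least squares, leaving
an optimization over $G$ (log-Cholesky factor, positive-definite by
construction) and the log level-1 variances. Per-child algebra uses the
relative-factor Woodbury identity
$V_i^{-1} = R_i^{-1} - R_i^{-1} Z_i L (I + L'Z_i'R_i^{-1}Z_i L)^{-1}
L'Z_i'R_i^{-1}$ with $G = LL'$, which stays numerically stable as $G$
approaches singularity (no inverse of $L$ is ever formed) — essential
because overparameterized candidates in model selection are routinely
driven to near-singular $G$. For the segmented structure, per-child
per-band cross-products of $[Z\; X\; y]$ are precomputed once per fit, so
one likelihood-plus-gradient evaluation costs $O(q^3 + q^2 p)$ per child
regardless of the number of measurement rows. Gradients are analytic.

Starting values come from a method-of-moments pass (covariance of
ridge-stabilized per-child OLS coefficients, per-band residual
variances) followed by expectation-maximization updates of $(G, \sigma^2)$
until the log-likelihood gain drops below 0.5; quasi-Newton optimization
finishes the job (L-BFGS-B for small parameter vectors, `nlminb`
otherwise, with restarts until the scaled gradient criterion is met).
Design columns are internally rescaled to unit root-mean-square; results
are reported on the original scale, with the REML log-likelihood
corrected for the scaling so candidates with different bases remain
comparable. Convergence is declared when `max|gradient| / n_obs < 1e-4`;
screening fits during model selection use a relative objective tolerance
of `1e-7` and final fits `1e-8`, both far below the criterion gaps that
selection decisions rest on. The tolerances and the 95% normal-quantile
confidence level are package choices; they are not dictated by the
methodology.

## Trajectory bases

Fractional polynomials of degree 1 and 2 use powers
$\{-2, -1, 0, 0.5, 1, 2, 3\}$, power 0 meaning $\log t$ and a repeated
power $(p, p)$ contributing $(t^p, t^p \log t)$: 7 degree-1 candidates
plus 28 unordered degree-2 pairs, 35 in all. Because several transforms
are undefined at age 0, a one-year offset is added to age before the
transform whenever a non-positive or repeated power is present; the
offset is recorded in the specification. Restricted cubic splines
(linear before the first and after the last knot) use the truncated-power
basis normalized by $(k_K - k_1)^2$ so coefficients share a scale, with
3–7 knots placed at Harrell's percentile sets of the *measurement-level*
age distribution (placement on child-level ages is a defensible
alternative; measurement-level is used because the model is fitted to
measurements).

## Two-stage model selection

Selecting among 40 candidate trajectory models on the full pooled data
would be prohibitively slow, while per-cohort selection is biased toward
simple shapes. Two devices address this:

* **Summed likelihood**: fit the same candidate separately to every
  cohort and add the log-likelihoods. This works for fractional
  polynomials but *structurally fails* for splines when cohorts cover
  different age ranges — a knot at 10 years cannot exist inside a cohort
  observed only to age 5 — and the package raises exactly that error.
* **Random-sample selection** (the default): draw a child-level random
  sample whose cohort composition matches the pooled data
  (largest-remainder rounding), select on it, and use the unselected
  children as a validation set.

Stage 1 selects the trajectory form: every candidate is fitted by ML on
the selection sample with intercept + trajectory fixed effects, full
individual-level random effects, and two independent measurement-level
variances for ages $\le 2$ and $> 2$. Candidates are ranked within family
by BIC (AIC is also reported; the ranking criterion is configurable
because the methodology names both), the top 2 per family go forward, and
the winner is the shortlisted candidate with the smallest validation-set
mean squared prediction error, computed with fixed effects only since new
children have no estimated random effects. Because MSPE is continuous, a
literal tie never occurs; ties are defined by the one-standard-error
rule: candidates whose MSPE lies within one standard error of the paired,
child-clustered MSPE difference from the best candidate are treated as
tied, and ties resolve toward fewer parameters, then canonical candidate
order. (Without this, family comparisons between a true fractional
polynomial and a 7-knot spline that approximates it to a fraction of a
percent would be decided by noise.) Non-converged candidates are
excluded and flagged. Stage 2 re-fits the winning trajectory by REML
under each level-1 variance structure (REML comparisons are valid here
because the fixed effects are identical) and ranks by the same criterion.

**Interaction pruning.** A covariate level observed only at ages where a
spline column is identically zero (the column's knot exceeds the
cohort's window) makes that covariate-by-trajectory interaction
unidentifiable. The package counts, for every covariate level and
trajectory column, the children and measurements carrying that level
inside the column's support region (ages above the column's knot for
spline terms, everywhere for FP terms) and drops interactions below
configurable thresholds (defaults 30 children / 100 measurements). A
rank sweep over the assembled design then removes any remaining aliased
interaction columns — support counts cannot detect, for example, that
low-knot spline columns coincide with an affine function of age inside a
late-window cohort. Cohort-by-trajectory interactions are subject to both
rules; all drops are logged.

## Multiple imputation of child-level covariates

Complete-covariate analysis is doubly unattractive here: it discards
entire cohorts whose covariates were never measured, and when the chance
of complete covariate data depends on the observed outcomes it is biased.
Off-the-shelf joint-model imputation software cannot represent
age-dependent measurement variance, so the package implements an
iterative, trajectory-summary-based procedure:

1. Initialize missing values by draws from observed within-cohort
   category frequencies (pooled frequencies where a covariate is
   systematically missing).
2. Fit the full analysis model — including all its interactions — to the
   current completed data.
3. Compute each child's trajectory summaries. The default summaries are
   the child's *fitted trajectory values*
   $x_i(t)'\hat\beta + z(t)'\hat b_i$ at the quartile ages of the
   child's cohort, with $\hat b_i$ the empirical-Bayes random-effect
   prediction $\hat G Z_i'\hat V_i^{-1}(y_i - X_i\hat\beta)$. Fitted
   values track the child's observed data and are essentially invariant
   to the covariate values currently imputed for that child (the fixed
   and random parts compensate); using the raw residual $\hat b_i$
   instead (available as `summary_set = "eb"`) couples the summaries to
   the current imputations and was observed to destabilize the iteration
   — the fitted effect and the assignments can oscillate between
   attenuated and amplified states instead of converging.
4. For each incomplete covariate in turn, fit a multinomial-logistic
   model among children with the covariate observed — predictors: the
   other covariates' current values, cohort indicators where
   identifiable, and the trajectory summaries — draw coefficients from
   their asymptotic normal distribution, and draw each missing value
   from the implied category probabilities.
5. Repeat from step 2 for a fixed number of cycles (default 10; a
   coefficient trace is logged for convergence inspection); the final
   state is one completed dataset.

Because the *same* analysis model generates the summaries, the imputation
model sees the outcome information through exactly the lens of the
nonlinear trajectory and its interactions (a congeniality argument). For
a cohort where a covariate is systematically missing, its cohort
indicator is dropped from that covariate's imputation model — it is
unidentifiable there — so imputation borrows the covariate–summary
relationship from the observed cohorts; this is the only
MAR-consistent choice available. The parental education × occupation
composite is never used as an imputation predictor for its own
components (it would leak the target deterministically); the components
stand in for it. Parameter draws use the asymptotic normal approximation
(a bootstrap is the obvious alternative); (near-)separation triggers a
ridge-penalized refit of the imputation model with a warning, and the
trajectory-summary predictors are standardized so the coefficient draws
stay well conditioned. Ethnicity in cohorts known to
be ethnically homogeneous is a harmonization constant, not an imputation
target.

$M$ completed datasets (default 25) are fitted by REML and pooled by
Rubin's rules: $\bar q$, within-variance $W$, between-variance $B$, total
$T = W + (1 + 1/M)B$, degrees of freedom
$(M-1)(1 + W/((1+1/M)B))^2$. The pooled result behaves like a fitted
model, so predicted trajectories and contrasts propagate the full MI
uncertainty.

## The synthetic data generator

The five restricted cohorts cannot ship with the package, so a generator
reproduces the *structure* the analysis must survive: five cohorts with
age windows 0–20, 0–5, 0–6, 9–18 and 0–16 years; visit schedules from 6
to ~55 target ages with Gaussian timing jitter (clamped to the window);
geometric per-visit dropout (monotone, MAR-compatible); one all-male
cohort; ethnicity distributions from homogeneous to majority South
Asian; and maternal education systematically missing in the two
historical cohorts. The default truth is a 5-knot restricted cubic
spline passing near (0, 3.5), (1, 10), (5, 18), (10, 32), (15, 55) and
(20, 62) kg — an infant spurt, mid-childhood slowdown and pubertal spurt
that no degree-2 fractional polynomial can reproduce, giving family
selection a recoverable target — with cohort contrasts that place the
school cohort markedly below the reference and the 0–16 trial cohort
0.93 kg below it at age 15, covariate effects of a few hundred grams,
and segmented level-1 variances of 0.25 kg² (infancy) and 2.25 kg²
(later). Sporadic covariate missingness is imposed by a logistic
mechanism in a per-child outcome summary (mean observed weight), making
it missing-at-random *given the outcomes* — the regime the imputation
procedure is designed for. Dropout hazards are free parameters, not
calibrated values: the real cohorts' dropout mechanisms are not public.

What the generator does **not** emulate: multiple births, measurement
source heterogeneity (clinic vs parental report), secular calendar-time
trends, cohort-specific age-at-entry patterns, and real-world departures
from normality. Passing validation studies on these synthetic data
therefore demonstrates correctness of the machinery under the stated
model, not robustness to everything real cohort data can do.

## Validation-study scales

The package's test suite runs the whole methodology at desk scale, chosen
so the full suite completes in minutes on one core while keeping each
check statistically sharp: likelihood values agree with a dense
multivariate-normal oracle to $10^{-8}$ on small random instances;
parameter recovery uses 20 replicate five-cohort studies of 2,000
children; trajectory-family selection consistency uses 20 seeds per
generating family with a 1,500-child selection sample (the real analysis
used 15,000 of 47,205); and MI validity uses 800-child studies with
$M = 5$ and 3 imputation cycles. Scaling down $M$ and the cycle count for
these studies is safe because the checks target point-estimate bias;
production inference should keep $M = 25$ and the 10-cycle default.

## Known limitations

* The level-1 structure assumes independence between measurement-level
  effects; serial correlation within a child beyond the random effects is
  not modelled.
* Extrapolation beyond each cohort's observed age support is refused by
  default (`allow_extrapolation = TRUE` overrides), because pooled
  trajectories are only identified where some cohort has data.
* The imputation model treats covariates as nominal; ordinal structure in
  education is ignored.
* Standard errors are model-based; no sandwich/robust variants are
  provided.
* The raw-to-harmonized category mappings shipped as defaults reflect the
  published harmonized vocabularies, but real deployments must supply
  their own mapping tables; combined education+occupation
  reclassification rules (needed for cohorts whose occupation categories
  cut across social classes) are expressible only as explicit mapping
  entries.
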