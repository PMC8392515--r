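---
title: "Modelling adolescent obesity with Bayesian, ML and PLS structural equation models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling adolescent obesity with Bayesian, ML and PLS structural equation models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

`obsem` implements a linear structural equation model of adolescent
obesity built around one question: how does a household's socioeconomic
position reach an adolescent's body composition?  Four latent constructs
are measured reflectively by 17 survey indicators:

* **household socioeconomic status** — age of father, age of mother,
  education of father, education of mother, income of mother, income of
  father;
* **lifestyle** — sleep duration, physical activity, screen time, pocket
  money;
* **healthy food intake** — fruits, vegetables, whole grains;
* **unhealthy food intake** — snacks, fast food, soft drinks, sweets.

Two observed outcomes, BMI and body fat, are modelled jointly.  The
socioeconomic construct acts on both outcomes directly and through three
mediators (lifestyle and the two food-intake constructs); parents' BMI
and parents' body fat enter as observed controls on the matching
outcome.  That gives 15 directed paths (13 structural, 2 control), and
the structural graph is a DAG.  Gender moderates every path: the model
is fitted separately per group and path coefficients are compared with
critical-ratio tests.

Writing $x$ for the indicator vector, $\eta$ for the latents and $y$ for
the outcomes, the measurement and structural parts are the usual
linear-Gaussian pair

$$x = \Lambda \eta + \varepsilon,\qquad
  \eta = B\eta + \zeta,\qquad
  y = \Gamma\eta + \gamma c + e,$$

with diagonal residual covariances.  The source survey never writes
these equations; the matrix formulation here is the package's own, and
all reporting is in the fully standardized metric (unit-variance latents
and observed variables), which is how the survey reports loadings and
paths.

### Identification

Latent scales are identified by fixing variances rather than anchor
loadings, because every loading is reported standardized.  Internally
the samplers and optimizers work on a convenient raw scale (unit
*disturbance* variances for the Gibbs sampler; unit exogenous-latent
variance with free endogenous disturbances for ML) and every retained
draw or point estimate is mapped to the fully standardized solution.
Signs are pinned by requiring each construct's first loading to be
positive — in the Gibbs sampler this flip is applied at every sweep.
Likert-type items are treated as continuous after z-standardization,
matching how the survey reports conventional loadings and alphas.

## Synthetic data: what it emulates and what it does not

The survey's raw data are not publicly available, so the package ships a
generator whose defaults *are* the published study conditions:

* total sample 881 (the completed questionnaires), split evenly between
  boys and girls — the survey does not report its group sizes, so 0.5 is
  the neutral choice and is configurable;
* the 17 reported standardized loadings (including the three weak
  socioeconomic indicators at 0.48, 0.32 and 0.46, so the reliability
  screen has something to find);
* the group-specific standardized path coefficients of the boys' and
  girls' models (e.g. socioeconomic → healthy food intake 0.41 for boys,
  0.61 for girls);
* residual and disturbance variances are not published anywhere; they
  are derived from the unit-variance convention (residual = 1 −
  explained variance for every variable), the only choice consistent
  with a fully standardized reported solution.

Data are drawn continuously (Gaussian); `discretize_likert()` can cut
indicators into ordered categories but is off by default since every
estimator treats indicators as continuous.  The generator reproduces
first and second moments and the multivariate normal shape of the
implied model.  It does *not* emulate ordinal coarseness, skewness,
item non-response, school-level clustering, or any misfit between the
published model and the underlying population — so passing recovery
tests demonstrate the estimators are correct for the model class, not
that the model is right for real adolescents.

Generated outcomes are standardized (mean zero).  One practical
consequence: the mean absolute *percentage* error is a poorly behaved
metric on such data (observed values near zero inflate it), which is why
the comparison tables report it alongside — but never instead of — RMSE
and MAE.

## The three estimators

**Gibbs sampler (Bayesian).**  Conjugate normal priors on loadings and
path coefficients (prior variance 1 by default — a deliberately "small
variance" that keeps the prior regimes meaningful; 100 under
`diffuse_prior()`), inverse-gamma(0.01, 0.01) on residual variances.
The sweep cycles through (a) latent scores from their exact Gaussian
conditional given all observed variables, (b) loadings and structural
coefficients from conjugate normal regressions given the scores, and
(c) residual variances from conjugate inverse-gamma updates.  Point
estimates are posterior means; posterior SDs use the population
(divide-by-N) convention, and 95% intervals are equal-tailed.  The
default run is 2 chains × 10 000 sweeps with 5 000 burn-in; at this
model size the mixing check in the test suite holds split-half R-hat
below 1.05 already at 1 500 sweeps, which is why the calibration suites
use chains of about that length.

The hyperparameter regimes for prior sensitivity mirror the published
design: a base ("Type I") set of prior means for the eight
latent-to-outcome paths (different for boys and girls, loading mean
0.5), a halved ("Type II") and a doubled ("Type III") version.  With
n = 2000 the three regimes move no structural estimate by more than a
few hundredths, which is the robustness property the sensitivity table
is built to show; at n = 10 the prior visibly dominates, as it should.

**Maximum likelihood.**  The classical discrepancy
$F = \log|\Sigma(\theta)| + \mathrm{tr}(S\Sigma^{-1}(\theta)) - \log|S| - p$
is minimized by multi-start quasi-Newton (`nlminb`) with an analytic
gradient computed from the reticular-action form of the model; jittered
starts come from a private RNG stream so a fit is a deterministic
function of data and `start_seed`.  Standard errors come from the
expected information at the optimum; standardized-solution SEs use the
delta method with a numerical Jacobian of the standardization map.
`chisq = (n-1) F` with `df = p(p+1)/2` minus the number of free
parameters (175 for the full 21-variable model).  The baseline for
incremental fit indices is the independence model, whose discrepancy is
`-log det` of the sample correlation matrix.

**PLS.**  The survey names PLS without a variant, so the package uses
the classical default: Mode-A outer weights, centroid inner scheme,
tolerance 1e-6, at most 300 iterations, then OLS path coefficients on
the standardized composite scores.  PLS composites are deliberately not
treated as a generative model: no SEs, no `simulate()`.  Two biases are
documented facts of the method, and the test suite bounds both: weak
indicators' loadings are inflated (each indicator's own noise enters its
composite; bounded at 0.15 from the generating values), and structural
paths can differ systematically from ML even at n = 5000 (bounded at
0.15 on the worst path of the girls' model).

**Predictions** for ML and Bayes use regression-method factor scores
(the conditional mean of the latents given the indicator block) — the
choice that minimizes mean-squared score error and therefore matches a
predictive-metric comparison; PLS uses its native composite scores.
Outcome predictions are the fitted structural equations applied to
scores plus controls, returned in original units.

## Measurement screening

`reliability_filter()` applies the conventional three thresholds:
standardized loading > 0.7 (an indicator strictly below is eliminated;
exactly 0.7 is retained), Cronbach's alpha > 0.7 and AVE > 0.5.
Loadings entering the screen come from a per-construct single-factor
fit (ML factor analysis, with an exact closed form for two-indicator
constructs), a modular choice that keeps the screen independent of the
structural model.  On data generated at the published loadings the
screen eliminates exactly the three weak socioeconomic indicators (both
parents' ages and the mother's income).  The published per-construct
AVE values themselves cannot be reproduced from the published loadings
under any subset we tried, so the package treats AVE as a derived
quantity, never as an oracle.

## Numerical choices and edge cases

* Residual variances of exactly zero are admitted in parameter sets
  (they arise in noise-free limiting oracles); factor scoring falls
  back to a pseudo-inverse, which recovers latents exactly when
  indicators are noiseless.
* Non-positive-definite implied covariances, zero-variance columns,
  missing cells and singular sample covariances are rejected with the
  offending variable named, before any estimator runs.
* A standardization that would need negative residual variance
  (explained variance ≥ 1) is rejected with the variable named.
* The moderation test uses unpooled SEs from each group's own fit —
  the standard critical-ratio form — and is antisymmetric in the group
  order by construction.
* Tables are written at two decimals (the survey's precision); JSON
  artifacts keep full precision.  Reruns of `run_full_study()` with the
  same configuration are byte-identical on every numeric CSV.

## Problem sizes used by the validation suites

Chosen as the package's own benchmark design: moment convergence at
n = 10⁵–10⁶; Gibbs recovery at n = 2000 with 50 replicates (all 15
structural paths within ±0.10 of truth in at least 95% of replicates);
prior-regime robustness at n = 2000 (max gap < 0.05 per path);
Bayes–ML agreement at n = 5000 (< 0.03 per structural path); and
type-I calibration of the moderation test at 441 per group with 1000
replicates (per-path rejection rate 0.05 ± 0.02), run with warm-started
ML fits because a thousand MCMC runs would buy no additional
information about a z-test's calibration.

## Known limitations

* Indicators are modelled as continuous; a probit/ordinal measurement
  model is out of scope.
* Complete cases only — no missing-data augmentation.
* No measurement-invariance (configural/metric/scalar) testing before
  group comparison, mirroring the source design.
* No discriminant-validity matrix; the screen applies the three
  univariate thresholds only.
* PLS standard errors (bootstrap) are not implemented; moderation
  inference uses Bayes or ML fits.
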