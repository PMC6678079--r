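---
title: "Joint modelling of paired driver injury severities in rear-end crashes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of paired driver injury severities in rear-end crashes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rpbivop)
```

## The problem

In a rear-end collision between two passenger cars, two drivers are injured
by the *same* event.  Police-reported injury severity is ordinal (the KABCO
scale, regrouped here to four levels: L1 no injury, L2 possible injury, L3
non-incapacitating evident injury, L4 incapacitating or fatal), and the two
drivers' outcomes are correlated: they share the light condition, road
surface, impact speed and — critically — unobserved circumstances that no
covariate captures.  Modelling each driver with a separate ordered probit
ignores that correlation; pooling the two drivers into one equation ignores
their systematically different exposure (the struck, front driver is injured
far more often than the striking, rear driver).

`rpbivop` implements the model class built for exactly this situation: a
**bivariate ordered probit** with **random (mixed) coefficients**, estimated
by **maximum simulated likelihood** with scrambled Halton draws.

## Model

Each driver $j$ ($j=1$ rear/striking, $j=2$ front/struck) in crash $i$ has a
latent injury propensity

$$y^*_{ij} = \beta_j' x_{ij} + \varepsilon_{ij},$$

censored into the observed level $y_{ij} = c$ when
$\mu_{j,c-1} < y^*_{ij} \le \mu_{j,c}$, with thresholds
$-\infty = \mu_{j,0} < \mu_{j,1} < \dots < \mu_{j,K} = +\infty$.  The two
error terms follow a standard bivariate normal with correlation $\rho$, so
the probability of an outcome pair $(k, l)$ is the four-term rectangle
combination of the bivariate normal CDF $\Phi_2$ evaluated at the
threshold-minus-index corners.  Unobserved heterogeneity enters through
random coefficients, $\beta_{i} = \beta + \gamma_i$ with
$\gamma_i \sim N(0, \sigma^2)$ independently per coefficient and crash; the
marginal likelihood integrates the rectangle probability over $\gamma_i$.

Identification follows the usual ordered-probit conventions: error variances
are fixed at 1, and in an equation with an estimated constant the first
interior threshold is fixed at 0 (a four-level outcome then has two free
thresholds per equation, reported as $\mu_1, \mu_2$).

Interval censoring is implemented with half-open intervals
($\mu_{c-1} < y^* \le \mu_c$).  The boundary event has probability zero, so
this choice does not affect the likelihood, but it makes simulation
deterministic.

## Estimation

`fit_rpbop()` follows the standard two-step protocol:

1. **Starting values.**  Two univariate ordered probits are fitted
   separately (`fit_univariate_op()`, via `MASS::polr`, remapped to this
   package's parameterization; intercept-only models use the closed form).
   Random-coefficient standard deviations start at 0.1 and $\rho$ at 0.
2. **Maximum simulated likelihood.**  For each crash the joint cell
   probability is averaged over $R$ quasi-random realizations of the random
   coefficients, and the summed log of the averages is maximized.  One draw
   set (`halton_draws()`) is generated per fit and reused for every
   likelihood evaluation: consecutive prime bases per random coefficient,
   the first 50 points dropped, a seed-controlled random shift modulo 1, and
   an inverse-normal transform.  Draws vary by crash, not by driver; the two
   equations use disjoint Halton dimensions, and random coefficients are
   mutually independent (cross-equation dependence enters only through
   $\rho$).

The optimizer (`nlminb`, quasi-Newton) works on an unconstrained scale:
$\log \sigma$, threshold gaps as cumulative exponentials above the fixed
cutoff, and $\mathrm{atanh}\,\rho$ — so $\sigma > 0$, ordered thresholds and
$|\rho| < 1$ hold by construction.  Gradients are one-sided finite
differences during the search; convergence is certified with a
central-difference gradient of the *mean* (per-crash) log-likelihood, with
max-norm tolerance `tol` (default `1e-5`).  The per-crash scale makes the
tolerance meaningful independently of the sample size; on the total
log-likelihood the same threshold would sit below the attainable
finite-difference noise floor.  With random coefficients present the search
first converges on a coarse draw set (`warm_start_draws`, default 50) and
then polishes on the full `R` draws — a standard economy in simulated
likelihood work; all reported quantities come from the full draw set.

Standard errors are square roots of the diagonal of the inverse numerical
Hessian (central differences, step $10^{-4}\max(1,|\theta|)$) of the total
simulated log-likelihood, delta-mapped from the transformed to the natural
scale.  A random standard deviation that collapses to the zero boundary
(below `sigma_floor`, default $10^{-3}$) has no curvature in $\log\sigma$;
its coordinate is profiled out of the Hessian, its standard error is
reported as missing, and `prune_random_params()` treats it as
non-significant by fiat.

**Pruning.**  Following common practice, a random coefficient whose
estimated standard deviation is not significant (two-sided p-value above
`sd_alpha`, default 5%) is refitted as a fixed coefficient;
`prune_random_params()` iterates this one coefficient at a time (least
significant first) until all remaining standard deviations are significant.
The screening of candidate covariates in separate univariate models is
conventionally done at the 10% level; both levels are configuration keys.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `R` | 200 | Halton draws per crash; simulation noise shrinks roughly as $1/R$ for quasi-random sequences.  200 is the common desk-scale choice in the mixed-model crash literature. |
| `warm_start_draws` | 50 | coarse first-stage draw count (0 disables) |
| `tol` | 1e-5 | max-norm of the per-crash mean gradient at convergence |
| `max_iter` | 500 | quasi-Newton iteration cap per stage |
| `sd_alpha` | 0.05 | significance level for the SD pruning rule |
| `sigma_floor` | 1e-3 | boundary below which a random SD counts as collapsed |
| `seed` | 1 | Halton scramble seed |

## The synthetic-data generator

No public microdata accompany the national crash-sample extract the model
class was developed on, so `rpbivop` ships a generator that emulates its
statistical structure end to end:

- `covariate_scheme()` / `generate_covariates()` draw 0/1 dummies at
  specified prevalences.  Covariates are either *crash-shared* (hour, light,
  season, region, roadway — identical for the two drivers) or
  *driver-specific* (age group, sex, airbag, belt use, model year — drawn
  independently per driver).  Mutually exclusive dummy groups (age bands,
  model-year bins, regions) come from one categorical draw with the
  remaining mass on the implicit reference level.
- `table2_scheme()` fixes the default prevalences at the published sample's
  marginal rates (e.g. male 14,211/30,318 drivers, nighttime
  5,238/30,318); layout variables reported only graphically in the source
  use plausible rates chosen once (divided roadway without median 0.15,
  with median 0.25, one-way 0.05, ramp 0.03, summer 0.25, Monday 1/7).
- `simulate_outcomes()` draws the two latent errors from the
  Cholesky-factored bivariate normal, adds normal random-coefficient
  deviations for coefficients with $\sigma > 0$, and censors through the
  thresholds.  Errors are drawn before coefficient deviations so that a
  model with all $\sigma = 0$ reproduces the fixed-parameter generator
  bit-for-bit under the same seed.
- `table1_fixture()` and `table3_truth_fixture()` package the published
  joint outcome table and final estimates as data objects, giving the test
  suite a realistic ground truth (`table3_spec()` carries the matching
  equation structure).

What the generator does *not* emulate: covariate dependence beyond shared
scope (the source tabulates drivers by their own injury level only, not a
joint covariate distribution), survey design weights, and within-region or
temporal clustering.  Passing recovery tests on these data therefore
demonstrates correctness of the estimator under the model's own assumptions,
not robustness to real-data misspecification.

## Numerical choices

- $\Phi_2$ uses Gauss–Legendre quadrature of the Drezner–Wesolowsky
  single-integral representation with Genz's node schedule (6/12/20 nodes by
  $|\rho|$) and the complementary series formulation near $|\rho| = 1$;
  absolute error is near machine precision, verified in tests against
  adaptive quadrature of the conditional-normal representation and
  Monte-Carlo integration.  Infinite rectangle corners are evaluated as
  exact univariate limits.
- Cell probabilities are floored at $10^{-300}$ before logs; floored cells
  are counted and surfaced (`clamp_count`) instead of silently producing
  $-\infty$.
- The likelihood core detects crashes whose random-coefficient covariates
  are all zero (common with sparse dummies) and evaluates their
  draw-invariant cell probability once instead of $R$ times.

## Scale of the shipped simulation studies

The test suite exercises parameter recovery at 10,000 crashes with $R=200$
(one full replication with standard errors, four sign-only replications),
pruning at 900 crashes with $R=25$ on a three-level outcome, and
distributional checks at $10^5$–$10^7$ draws; the acceptance script refits
the printed joint table (15,159 crashes) and a 6,000-crash synthetic
recovery.  These sizes were chosen to finish on a single desk CPU while
keeping Monte-Carlo error well inside the asserted tolerances.

## Known limitations

- Random coefficients are mutually independent; correlated mixing
  (Cholesky-structured $\gamma$) is out of scope, as are more than two
  equations, non-normal errors and heteroskedasticity.
- Marginal effects and elasticities are not computed.
- Standard errors near the $\sigma = 0$ boundary are conditional on the
  collapsed coefficients being fixed; a boundary-corrected likelihood-ratio
  test is not provided.
- The simulated log-likelihood is a biased (upward) estimate of the true
  mixed log-likelihood at finite $R$; comparisons across $R$ should use the
  same draw seed.
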