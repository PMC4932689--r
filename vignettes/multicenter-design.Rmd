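---
title: "Designing multicenter binary-outcome trials under treatment-by-center interaction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Designing multicenter binary-outcome trials under treatment-by-center interaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The design problem

A multicenter two-arm randomized trial measures a binary outcome — the
motivating example is preterm birth (delivery at or before 33+6 weeks) in
women with a short cervix, with a cervical pessary added to standard care in
the treatment arm. The control-arm event probability is not one number: it
varies between clinical centers with patient mix, referral patterns and local
practice. When the treatment effect is measured as a risk difference, a
treatment that multiplies everyone's risk by the same factor still produces
*different* risk differences at centers with different baseline risks: the
between-center variation of the control probability is itself a
treatment-by-center interaction. Ignoring it understates the variance of the
pooled effect and undersizes the trial.

`mctrialsim` implements the full design workflow: a parametric model for the
between-center variation, a trial simulator, a random-effects analysis, an
empirical power engine with a sample-size search, a closed-form variance
decomposition for sensitivity analysis, and a Bayesian decision model that
carries the trial's effect on the surrogate outcome through to the rare
clinical outcome (perinatal mortality/morbidity) that the trial cannot be
powered for directly.

## The between-center model

Center `i`'s control-arm event probability `pi_Si` is modeled as a draw from
a Beta distribution, chosen because it is the natural conjugate family for a
probability and is fully determined by two interpretable quantities: the mean
`m` and the coefficient of variation `c` of the event probability across
centers. With `d = m/(1-m)` the odds of the mean, matching the Beta mean and
variance to `(m, c)` gives the closed form

    a = (1 - c^2 d) / (c^2 (1 + d)),    b = (1 - c^2 d) / (c^2 d (1 + d)),

which exists exactly when `c^2 < (1-m)/m`. `solve_beta_parameters()` errors,
naming that bound, for infeasible pairs.

```{r}
library(mctrialsim)
spec <- solve_beta_parameters(0.3, 0.3)
spec
tail_probability(spec, 0.225)       # fraction of centers above pi_T
beta_quantiles(spec, c(0.05, 0.95))
```

For the base case (`m = 0.3`, `c = 0.3`) the shapes are `a = 7.478`,
`b = 17.45`; about 79% of centers have a control probability above the
treatment-arm probability 0.225; and 90% of the central mass lies in
(0.161, 0.457). A quoted "95% range" of (0.16, 0.46) for this distribution
matches these 5th/95th quantiles, not the equal-tailed 2.5/97.5 interval
(0.141, 0.490) — both are available from `beta_quantiles()`, and the package
does not privilege either reading.

Two deliberate representation choices:

* `cv = 0` is an explicit point-mass variant, not a limiting Beta. The
  CV = 0 row of a design table needs it, and a Beta with `a + b` near
  infinity is numerically awkward. Point-mass specs answer tail and quantile
  queries by direct comparison with the mean and consume no random numbers.
* Quantiles are computed with `stats::qbeta`, the numeric inversion of the
  regularized incomplete beta function. The test suite carries an
  independent bracketing/bisection inverter and checks agreement to 1e-8,
  so the inversion algorithm is verified rather than hand-rolled.

## The trial simulator

One simulated trial follows the intended conduct of the real one:

1. `n_total` patients are allocated at random among `k_centers` centers with
   equal probability, subject to every center receiving at least
   `min_per_center` patients (default 6). The constraint is honored by
   assigning the minimum to every center deterministically and distributing
   the surplus as an equal-probability multinomial — no rejection sampling,
   and the marginal allocation remains exchangeable across centers.
2. Within each center, randomization is stratified-blocked 1:1: half the
   patients to each arm, with an odd patient assigned by a fair coin flip so
   that neither arm is systematically favored.
3. Each center draws its latent control probability `pi_Si` from the
   between-center model; treatment-arm outcomes use a probability `pi_T`
   fixed across centers (default assumption), or center-specific draws when
   `treatment_arm_cv > 0` for robustness checks.
4. Event counts are binomial per center and arm.

Every stochastic entry point takes a seed, and replicate `r` of a run with
master seed `s` reseeds at `s + r`; candidate sample size `n` in the grid
search uses the seed block `s + (n/step) * 1e5`. Two consequences: reruns are
bit-identical, and any single replicate of any table cell can be reproduced
in isolation. Candidates share no streams, which avoids spurious
monotonicity artifacts from common random numbers (the variance-reduction
alternative — common random numbers across candidates — was considered and
set aside to keep candidate estimates independent).

## The random-effects analysis

The analysis allows the treatment effect to vary between centers. Each
center contributes a risk difference `rd_i = y_Ti/n_Ti - y_Si/n_Si` with
variance `p_T(1-p_T)/n_T + p_S(1-p_S)/n_S`; centers with a zero or full cell
get a continuity correction (0.5 per cell, 1 per arm total) applied to both
the estimate and the variance, which keeps inverse-variance weights finite
with centers as small as three per arm. The per-center effects are pooled
with the DerSimonian–Laird method-of-moments estimator, giving the pooled
risk difference `mu`, its variance `nu`, the between-center effect variance
`tau2` (truncated at zero), and a two-sided Wald normal test.

DerSimonian–Laird was chosen over a likelihood-based random-slope model
because it is closed-form — the power engine fits it ~10^5 times per
sample-size search — and because it lives natively on the risk-difference
scale that the downstream decision model requires. The normal (rather than
t) reference is appropriate with 20–100 centers. REML, Knapp–Hartung and
odds-ratio/log-RR scales are documented non-goals.

## Power and sample size

`estimate_power()` is the proportion of simulated trials reaching two-sided
significance; `find_sample_size()` walks a grid (default step 10 per arm,
start at the closed-form two-proportion approximation, here 536.4 → 540)
and returns the first grid point whose estimated power reaches the target.
The package default of 10,000 replicates per candidate matches the design
study being reproduced; the acceptance and test runs use that default, with
module tests using 200–4,000 replicates where only reproducibility or
monotonicity is at stake.

Computed at those sizes (by `scripts/acceptance.R` and the test suite): the
required size is ~550/arm with no between-center variation (closed form
536.4; the published simulation gives 540) and ~680/arm at CV 0.3 (published
700). The +130/arm penalty for interaction is reproduced; the residual
540-vs-550 and 700-vs-680 offsets are the expected footprint of the analysis
model. The original's random-effects estimator (fit in SAS) is unreported;
inverse-variance weighting of ~7-patient-per-arm centers with continuity
corrections has slightly different small-sample efficiency than any
likelihood-based alternative, and the grid's first-crossing statistic
carries ~1 grid step of Monte-Carlo noise near the target.

Two calibration facts, both computed by the acceptance tests, bound what
simulation results mean here:

* The Wald/DL test is asymptotically calibrated (type-I error 0.047 with 20
  centers of 400) but mildly anti-conservative at the base geometry of 80
  centers with ~7 patients per arm (0.058 at 10^4 replicates). This is the
  known small-stratum behavior of estimated inverse-variance weights; the
  package reports it rather than patching it with adjustments that are out
  of scope.
* The mean estimated `tau2` at 80 centers of 200 patients recovers the
  generating between-center effect variance `(0.3 x 0.3 x 0.3)^2 = 0.0081`
  within 5%.

The closed-form variance of the pooled risk difference under equal center
sizes,

    V = 2 (sigma_S^2 + sigma_T^2) / N + (v_S + v_T) / K,
    sigma_i^2 = pi_i (1 - pi_i),   v_i = (pi_i CV_i)^2,

drives `analytic_variance()` and `variance_sensitivity()`. Its structure
explains the design's behavior: the interaction penalty is divided by the
number of centers, not patients, so more centers shrink it; and the
treatment-arm contribution `v_T` is the square of a product of two small
numbers, so assuming `CV_T = 0` is robust (at the base case, `CV_T = 0.1`
raises `V` by 0.97%, `CV_T = 0.15` by 2.19%, against the 18.4% increase from
the control arm's `CV_S = 0.3`).

## From surrogate to clinical outcome

The trial is powered for preterm birth, a surrogate; the clinical endpoint,
perinatal mortality/morbidity, is ~30x rarer and would demand ~50x the
sample size. The decision model decomposes the between-arm difference in
the clinical outcome probability as

    Delta = (pi_ptb|T - pi_ptb|S) x (tau_pmm|ptb - tau_pmm|tb),

the surrogate risk difference times the contrast in clinical-outcome
probability given surrogate status. The decomposition assumes the two
conditional probabilities are the same in both arms — treatment changes
*whether* a baby is preterm, not the prognosis of a preterm (or term) baby.
That is the model's key substantive assumption, a weaker cousin of strict
surrogacy; the one-to-one limit (`tau_pmm|ptb = 1`, `tau_pmm|tb = 0`,
available via `fixed_link_delta_model()`) collapses `Delta` to the surrogate
effect exactly.

The two conditional probabilities get conjugate Beta posteriors from
external surrogate-link counts under uniform `Beta(1, 1)` priors; the
bundled MACS cohort counts (530 preterm / 166 events, 933 term / 5 events)
give `Beta(167, 365)` and `Beta(6, 929)`. The surrogate effect carries a
`Normal(mu, nu)` posterior taken from the trial's random-effects fit,
interpreted as the posterior under an uninformative normal prior — the
risk-difference scale is forced by the decomposition, and the DL fit is the
natural in-package source for `(mu, nu)`. `sample_delta()` multiplies
independent draws; `decision_summary()` reports the strictly-negative
fraction `P(Delta < 0)` and an equal-tailed empirical credible interval
(equal-tailed, not HPD, because a single interval convention had to be
fixed; ties at zero have probability zero under continuous draws).

`evaluate_decision_performance()` nests the whole pipeline — simulate trial,
fit, sample `Delta`, record the negative fraction — across many trials. At
the base case (700/arm, 80 centers, CV 0.3, MACS link) the acceptance test
computes a mean `P(Delta < 0)` of 0.978 with a 5th percentile of 0.888
across 1,000 trials of 2,000 draws, matching the published operating
characteristics 0.98 and 0.87. Off-base grid cells default to 1,000 trials
and 10,000 draws per cell (`table2_grid()`), both configurable.

## What the generator does and does not emulate

The defaults *are* the motivating study's conditions: control mean 0.3, CV
0.3 as the assessed upper bound, `pi_T = 0.225` (a 25% relative reduction,
number needed to treat ~13), 80 centers, minimum 6 per center, two-sided 5%
level, 80% power, 10,000 replicates. Simulated data are idealized: no
dropout, no missing outcomes, exact 1:1 balance within center, binomial
outcomes with a Beta between-center law, no secular trends, no
center-by-time effects, no correlation between center size and baseline
risk. Passing tests therefore certify the method and its operating
characteristics under the stated model, not robustness of a real trial to
violations of it.

Known limitations worth naming:

* The required size when the *clinical* outcome is primary (published as
  37,500/arm from a mean-0.01 control model) is reachable with the same
  machinery but is not reproduced as a validated result: the quoted
  generating distribution `Beta(9.9, 89.1)` implies a mean of 0.1, not
  0.01, under the moment formulas, so the package derives shapes from
  `(mean, cv)` only and treats that worked example as internally
  inconsistent.
* Full-scale design tables are minutes-to-hours of compute; the CLI's
  `--scale` (default 0.1) exists for desk runs and `--full` for replication.
* The search's returned size is defined by the first grid crossing at the
  configured replicate count; near-flat power curves make it a noisy
  statistic, which is why tolerances of one to two grid steps accompany any
  simulated sample-size claim.
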