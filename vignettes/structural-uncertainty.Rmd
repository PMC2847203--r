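---
title: "Parameter and structural uncertainty in Markov cost-effectiveness models"
author: "markovcea"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Parameter and structural uncertainty in Markov cost-effectiveness models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markovcea)
```

## The model

`markovcea` implements a discrete-time (daily cycle) multi-state model for
hospitalization and survival, built for cost-effectiveness analysis of an
implantable cardiac device against drug therapy, but applicable to any state
space of the same shape.  The base-case state space has eight states: alive
and out of hospital (state 1), hospital admission for six distinct causes
(states 2–7) and death (state 8, absorbing).  In one day a patient at home
can stay home, be admitted, or die; a hospitalized patient can stay, be
discharged, or die.

Transition probabilities follow a multinomial logistic regression.  For
patient $i$ in follow-up year $j$, the counts of one-day transitions out of
state $r$ are multinomial with probabilities $p_{ijrs}$, and

$$\log\left(\frac{p_{ijrs}}{p_{ijr1}}\right) = \mu_{rs} + \sum_k \beta_{rsk}\,x_{ijk},$$

with the out-of-hospital destination as reference.  Transitions are
aggregated by follow-up year so that time-dependent covariates (age) can be
treated as constant within a year.  Baseline covariates are treatment (drug
arm coded 1), sex, low ejection fraction, and country; age enters either as
a piecewise-constant effect (bands under 60, 60–70, 70 and over) or as a
polynomial in centred age.

Sparse-data constraints define the base case, labelled `M1`: the death row is
common to all source states (only a tiny fraction of deaths follow a hospital
day, so the data cannot identify state-specific death rows); length of
hospital stay depends only on country; and the drug-side-effect state has no
country effect (one country contributed no such admissions).  This yields 59
free parameters.  Candidate structures `M2`–`M10` vary the covariate sets and
the functional form of age (quadratic to quartic, with or without
age-by-treatment interactions); `build_model_config()` constructs each one,
and `build_parameter_index()` exposes the slot-to-parameter map (59, 71, 55,
54, 59, 66, 73, 73, 87, 101 free parameters for `M1`–`M10`).

## Inference

Priors are normal(0, 10) on every free parameter, except an informative
normal(0.414, 0.16) prior on the drug-vs-device mortality log odds ratio,
representing a fixed-effect meta-analysis of two earlier trials.  The
posterior is sampled by adaptive univariate random-walk Metropolis within
Gibbs (`sample_posterior()`): proposals adapt toward a 0.44 acceptance rate
during burn-in and are frozen afterwards, initial values are the prior means.
Any correct sampler would do — correctness here is defined by oracle tests
(a dense-grid posterior on a one-parameter model, prior-only runs, multi-seed
agreement), not by matching a particular algorithm.  The multinomial
normalizing constant is included in the likelihood so that per-row
likelihood values are genuine predictive probabilities; it cancels from all
between-model comparisons on the same data.

The observation unit for all per-observation quantities is one
(patient, year, from-state) multinomial row.  Grouping rows by patient
before bootstrapping is a defensible alternative reading; the per-row
convention is used throughout and the assessment exports are keyed by
(patient, year, from-state) so a per-patient aggregation is a one-line
`rowsum()` away.

## Cost-effectiveness

`expected_cost_benefit()` propagates the state-occupancy vector day by day,
$\pi_t = \pi_{t-1} P_t$, starting from probability 1 in state 1, with $P_t$
rebuilt as the patient ages (age advances by $1/365$ years per day and the
age covariates are re-derived).  Expected discounted cost is

$$E(C_u) = c_{0u} + \sum_{t=1}^{T} \rho^t\, \pi_t \cdot c_u,$$

and QALYs accrue analogously at utility$/365$ per day (0.75 in every alive
state, 0 for death) with identical discounting.  Conventions, where the
source material leaves room:

* the daily discount factor is $\rho = (1+a)^{-1/365}$ for annual rate $a$
  (3.5%/year by default); a year is 365 days everywhere;
* the initial cost $c_{0u}$ is not discounted (it is paid at day 0);
* no half-cycle correction is applied — none is part of the daily-cycle
  formulation;
* "age-dependent" utilities are a constant 0.75 by default (the utility
  vector is per-state and can be replaced);
* the typical patient is 63 years old, low ejection fraction, `female = 0.13`
  (a fractional covariate representing the cohort sex mix), country set to
  UK by default (configurable — the source populations span two countries);
* the horizon is a "lifetime" of 100 years (36 500 days).

`run_ce()` evaluates both policy arms at every posterior draw (the drug arm
switches both the treatment covariate and the initial/daily cost column), so
incremental cost and QALYs are sampled from their joint posterior with all
parameter correlations intact — one-stage probabilistic sensitivity
analysis.  `pce()` turns the draws into the probability of cost-effectiveness
at a willingness-to-pay $\lambda$ (and a CEAC over a grid); the ICER is the
ratio of posterior means, never the mean of ratios.

The hot loops (daily propagation, accumulation and microsimulation) are in
C++; the microsimulation (`simulate_ce_microsim()`) is retained as an
independent stochastic oracle for the cohort sum and is part of the test
suite, not just scaffolding.

## Predictive model assessment

Model structures are compared on expected predictive ability, not posterior
model probability — the candidate set is not assumed to contain the truth.
Two measures are computed from a single MCMC fit (`assess_fit()`):

* **CPO / PML.**  The conditional predictive ordinate of row $i$ is
  estimated by the harmonic mean of the per-draw likelihoods $f(x_i \mid
  \theta_r)$, the importance-sampling estimate that uses the full-data
  posterior as proposal for the leave-one-out posterior.  All arithmetic is
  in log space (log-sum-exp), stable for per-row log likelihoods of $-700$
  and beyond.  The estimator is known to be unstable when a few draws
  dominate; the package reports the largest single-draw weight share and the
  Monte-Carlo standard error of the running mean and warns above a 5% share,
  but applies no truncation.  The total $-2\log(\mathrm{PML})$ is validated
  against brute-force leave-one-out MCMC refits on a small model.
* **DIC.**  $p_D = \bar D - D(\hat\theta)$ and $\mathrm{DIC} = D(\hat\theta)
  + 2 p_D$, with the plug-in deviance evaluated at the posterior means of
  the per-row linear predictors $\log(p_{ijrs}/p_{ijr1})$ — the
  approximately-normal parameterization.  Because predictors are linear in
  the parameters this coincides with plugging in the posterior-mean
  parameters; the code path is the predictor-averaging one and the
  coincidence is asserted in a test.  The per-row decomposition
  $\mathrm{DIC}_i = \bar D_i + (\bar D_i - \hat D_i)$ sums exactly to the
  total.

DIC is typically below $-2\log(\mathrm{PML})$ (its utility ignores parameter
uncertainty); this is reported as a diagnostic, never asserted.

## Bootstrap model weights and averaging

Differences in PML or DIC between models carry sampling uncertainty.  The
Bayesian bootstrap (`bayesian_bootstrap_weights()`) draws observation
weights from a flat Dirichlet instead of resampling rows, so a replicate of
any sum-over-rows statistic is just a reweighted sum — no refitting.  The
selection probability of model $k$ (`selection_probabilities()`) is the
proportion of replicates in which it attains the highest log-PML (or lowest
DIC) replicate, with the same Dirichlet draw applied to every model within a
replicate (a paired comparison; independent draws would overstate
uncertainty).  Exact ties are split equally — this makes the single-model
and duplicated-model cases well defined (probability 1, and 0.5/0.5).
$B = 1000$ replicates by default.  The dependence among per-row
contributions through the shared posterior is ignored, as the method
assumes.  Weights proportional to PML or $\exp(-\mathrm{DIC}/2)$ are *not*
used for averaging; they are obtainable only as labelled diagnostics.

`model_average()` draws from the mixture posterior: pick a model with its
selection probability, then resample a draw of the functional (incremental
cost, QALY, net benefit).  A deterministic proportional block allocation is
available as an option (both estimate the same mixture).  Model-averaged
intervals are equal-tailed quantiles of the pooled sample.

## Synthetic cohorts

`simulate_cohort()` generates study-like data with known truth: staggered
uniform entry gives administrative censoring with mean follow-up 3.68 years
and maximum 7.04 (a uniform censoring time on 0.32–7.04 years); covariate
prevalences default to 13% female, 70% low ejection fraction, 55% one
country, 22% drug arm; starting age is truncated normal around 63.  The
generator advances age at follow-up-year boundaries (integer years), exactly
the granularity the yearly-aggregated likelihood assumes, and uses the same
`transition_probabilities()` code path as the fitter, so recovery failures
isolate the sampler rather than the generator.

The default ground truth (`default_true_theta()`) is a set of documented
constants, not estimates from any study: death intercept $-8.9$ (about
5%/year), admission intercepts $-8$ (about 0.1–0.2/year per cause),
week-scale hospital stays, mortality log odds ratio 0.414 for drug vs
device, no device-maintenance admissions in the drug arm, more drug-toxicity
admissions, and age effects that rise with age.  For the polynomial
variants, the quartic truth is a gently curved, steep-at-old-age log-odds
curve in centred age $(age-63)/10$ — coefficients $(0.55, 0.12, 0.05,
0.02)$ for death and $(0.3, 0.1)$ for admissions — chosen to be a plausible
mortality curve that a three-band step function cannot reproduce.  (An
earlier draft used a quartic that exploded at young ages, implying several
percent daily mortality for 35-year-olds; it was replaced on realism
grounds.)

What a green test establishes, and what it does not: the generator matches
the model family exactly (no model misspecification, no missing data, no
informative censoring, integer-age granularity), so passing recovery and
selection tests validates the estimation and comparison machinery — not the
fidelity of any model to real clinical histories.

## Numerical choices and test design

* Softmax and log-likelihoods use max-subtraction / log-sum-exp throughout;
  the contract is finite output for log odds up to $|700|$.
* $0\log 0 \equiv 0$ in the multinomial likelihood.
* Rows with identical from-state and design vector are collapsed before MCMC
  (the yearly rows of patients sharing covariates and age band are
  exchangeable), which makes sweeps cheap without changing the posterior;
  the multinomial constants are accumulated once from the uncollapsed rows.
* The sampler's iteration convention follows the reporting of the motivating
  analysis: `n_iter` kept draws after `n_burnin` discarded adaptation
  iterations (the full-scale preset is 25 000 kept after 5 000 burn-in; the
  test profile is much smaller and is noted in each test).
* Model-selection power checks use cohorts of 600 patients: a power probe
  during development showed the pseudo-marginal likelihood separates the
  quartic-age truth from the piecewise base case reliably at that size
  (selection probability about 0.94), while 300 patients are too few for a
  stable preference.
* The acceptance suite scales simulations down where the criterion permits
  (a 15-year horizon for the microsimulation comparison; 2 500 kept
  iterations for the recovery study) and says so inline.

## Known limitations

* The harmonic-mean CPO estimator is reported with stability diagnostics but
  no stabilization; for models with influential single rows the PML totals
  should be read alongside the dominance warnings.
* Continuous-time (intensity-based) multi-state models, semi-Markov sojourn
  distributions, hierarchical random effects, missing-data imputation and
  reversible-jump exploration of the model space are out of scope.
* Marginal likelihoods / posterior model probabilities are deliberately not
  computed: the framework treats all candidate structures as approximations.
* Comparing models defined on different state spaces (merged or removed
  states) is not supported — their likelihoods are not on a common scale.
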