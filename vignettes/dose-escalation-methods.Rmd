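---
title: "Model-guided dose escalation with crmdose: models, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-guided dose escalation with crmdose}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmdose)
```

## The dose-finding problem

A phase I oncology trial administers one of $K$ ordered dose levels to each
patient and observes a binary dose-limiting toxicity (DLT) during a fixed
observation window. The maximum tolerated dose (MTD) is the level whose DLT
probability is closest to a target $\theta$ (CRM family) or the largest
level whose posterior probability of exceeding the MTD stays below a
feasibility bound $\alpha$ (EWOC family). All designs in this package share
the same skeleton (prior DLT probability per level), the same weighted
binomial likelihood, and the same no-skip escalation cap; they differ in the
model, the estimation method, and the selection rule.

## Models and standardized doses

Three dose–toxicity families are provided. The empiric (power) model
$\psi(x,a) = x^{\exp(a)}$ uses the skeleton probabilities themselves as its
standardized doses $x_i \in (0,1)$, so the skeleton is the single
user-facing prior object. The one-parameter logistic
$\psi(x,a) = \mathrm{logit}^{-1}(b + e^a x)$ uses
$x_i = \mathrm{logit}(p_i) - b$, with the fixed intercept defaulting to
$b = 3$, the long-standing convention for one-parameter logistic CRM. The
two-parameter logistic $\psi(x,a_0,a_1) = \mathrm{logit}^{-1}(a_0 + a_1 x)$
with $a_1 > 0$ underlies EWOC and uses $x_i = \mathrm{logit}(p_i)$. All
three are strictly increasing in dose for valid parameters, which the test
suite checks by property over randomly drawn parameters.

## Skeleton calibration

`calibrate_skeleton()` builds the prior by the indifference-interval
construction: level $\nu$ (the prior guess of the MTD) is anchored exactly
at $\theta$, and adjacent levels are spaced so that the parameter value
mapping level $i{+}1$ to $\theta+\delta$ maps level $i$ to $\theta-\delta$.
For the empiric family this gives the closed recursion
$p_{i+1} = \exp\{\log(\theta+\delta)\log(p_i)/\log(\theta-\delta)\}$ upward
and its inverse downward; for the one-parameter logistic the same boundary
conditions are linear on the working-dose scale, so a closed-form ratio
recursion applies there too (no numerical root-finding turned out to be
necessary for either family). With $\theta = 0.2$, $\delta = 0.05$,
$\nu = 3$, $K = 6$:

```{r skeleton}
calibrate_skeleton(theta = 0.2, delta = 0.05, nu = 3, K = 6)
```

The halfwidth $\delta$ controls how fast the skeleton spreads around the
target: larger values make the design less willing to move, smaller values
make adjacent levels nearly indistinguishable. $\delta$ must satisfy
$0 < \delta < \min(\theta, 1-\theta)$; the $\delta \to 0$ limit collapses
every level onto $\theta$ and is rejected as a degenerate skeleton.

## Likelihood, weights and posteriors

Every design maximizes or integrates the weighted binomial likelihood
$$L(a) = \prod_l [w_l\,\psi(x_l,a)]^{y_l}\,[1 - w_l\,\psi(x_l,a)]^{1-y_l},$$
with all weights equal to 1 for complete-observation designs. Time-to-event
designs use the linear weight $w = u/T$ for a patient followed $u$ out of
the window $T$ without DLT, and exactly 1 on a DLT. Weights are recomputed
from `(followup, window, outcome)` at every estimation call, never cached,
because follow-up updates are the core of TITE conduct. A pending record
with $u = 0$ has weight 0 and contributes nothing; a pending outcome in a
complete-observation design blocks the next model-based recommendation
rather than being silently dropped.

Bayesian posteriors are computed by deterministic trapezoid quadrature:
2001 nodes spanning the prior mean $\pm 8$ prior standard deviations,
clipped to the prior's support, with all likelihood evaluation in log
space. This is fast (a fit costs a fraction of a millisecond), exactly
reproducible, and easy to check against Monte-Carlo oracles — the test
suite compares posterior means and integrated estimates against
self-normalized importance sampling with $10^6$ prior draws. The only
visible cost of truncation is at unbounded skewed priors: under the
unit-exponential prior the prior mean is reproduced to about $10^{-3}$
rather than machine precision.

Two per-level estimate conventions are exposed. The *integrated* estimate
$\hat\psi(x_i) = \int \psi(x_i,a) f(a\mid\Omega)\,da$ averages the curve
over the posterior; the *plug-in* estimate $\psi(x_i,\hat a)$ evaluates it
at the posterior mean. The integrated form is the package default: it is
the fully Bayesian quantity, and it is the convention under which the
simulated operating characteristics below reproduce the published
reference table (the plug-in variant shifts roughly one patient of
allocation from level 6 to level 5 under that scenario). Both are always
computed and `dose_tox_estimates()` switches between them.

The default parameter prior for Bayesian CRM is normal with mean 0 and
variance 1.34, the operational standard for one-parameter CRM;
unit-exponential, gamma, uniform and lognormal priors are available through
`prior_spec()`.

Maximum-likelihood estimation (CRML) requires at least one DLT and one
non-DLT with positive weight; until then the likelihood has no finite
maximizer and the design runs algorithmically (`crml_run_in()`): escalate
one level per DLT-free cohort from the starting level, hold the level after
the first DLT, and hand off to the MLE once both outcome kinds exist. The
run-in cohort size defaults to 1 (single-patient escalation) and is
configurable to 3 for a 3+3-style run-in; the choice is left open because
practice varies and the published description names 3+3 only as an example.

## EWOC

EWOC reparameterizes the two-parameter logistic as $(\rho_0, \gamma)$: the
DLT probability at the lowest dose and the MTD location on the working-dose
axis. The joint posterior lives on a fixed $201 \times 201$ trapezoid grid
with $\rho_0 \in (0, \theta)$ and $\gamma \in [x_1, x_K]$ (the first
$\gamma$ node is nudged inward to avoid the degenerate step curve at
$\gamma = x_1$). The default priors are independent uniforms on those
ranges; gamma, uniform and lognormal alternatives are configurable. The
overdose probability $\pi(x) = P(\mathrm{MTD} \le x \mid \Omega)$ is the
marginal distribution function of $\gamma$, and `ewoc_next_dose()` selects
the highest level with $\pi(x) \le \alpha$, falling back to level 1 when
none qualifies. The feasibility bound is held fixed over the trial;
schedules that increase $\alpha$ with accrual are out of scope. The grid
posterior is validated against a rejection-sampling oracle in the tests.

## Dose selection and stopping

CRM selection takes the level whose estimate is closest to $\theta$,
breaking ties — within a $10^{-10}$ numerical guard — toward the lower,
safer level. The no-skip constraint caps every recommendation at one level
above the highest level tried so far and is ON by default for all designs:
the published interface exposes it only for EWOC, but applying it uniformly
is the safe generalization and it never binds for the Bayesian CRM under
the scenarios studied here. Two stopping rules are implemented: maximum
sample size, and "m patients already treated at the level about to be
recommended" (the fixed-level reading of that rule is also supported,
because the published phrase "a certain dose level" admits both; the
recommended-level reading is the default).

## Trial conduct

`trial_start()` creates a stateful trial whose design is frozen at the
first inclusion. Inclusions, pending-outcome resolutions, follow-up
advances and audited corrections each append an ISO-8601 UTC entry to an
append-only audit log; corrections require an explicit reason and trigger a
full deterministic replay of the recommendation sequence from the raw
history. The clinician may override the recommended level, and both the
recommendation and the administered level are stored. Persistence is a
single JSON document with a mandatory `schema_version` (files from a newer
schema are refused); exports are plain CSV. Batch entry is restricted to
time-to-event designs — where continuous accrual makes it useful — and is
atomic: one malformed row rejects the whole batch.

## Simulation and its assumptions

`run_batch()` evaluates a design by Monte Carlo. One root seed is expanded
into per-trial substreams drawn up front, so results are independent of
execution order and identical across repeated runs. Complete-observation
trials resolve each outcome before the next enrollment (staggered accrual).
TITE trials enroll on a fixed accrual clock, defaulting to one third of the
observation window between arrivals, and draw the time to DLT (given a DLT)
uniformly on $(0, T]$; both choices are documented defaults rather than
claims about any particular trial, since accrual and toxicity-timing
processes are trial-specific. Simulated patients always follow the model
recommendation — the generator emulates protocol-faithful conduct, not
clinician overrides, inter-patient heterogeneity, or mid-trial skeleton
changes, so passing operating characteristics say nothing about those
features of real conduct.

The reference configuration used by `scripts/acceptance.R` and the
acceptance tests is the motivating six-level scenario: skeleton
(0.049, 0.111, 0.200, 0.308, 0.423, 0.534), target 0.2, start level 3,
25 patients per trial, 1000 replicates, true toxicity probabilities
(0.003, 0.016, 0.047, 0.107, 0.196, 0.305). The published table for that
scenario does not state the model family or estimator convention; we ran
the candidate configurations at 1000 replicates across several seeds and
adopted the one-parameter logistic with integrated estimates, which
reproduces all eight published quantities (MTD percentages at levels 3–6
and average patients at levels 3–6) within Monte-Carlo noise, whereas the
empiric/plug-in combinations misplace up to 1.4 patients of allocation
between the top two levels. The problem sizes (1000 trials of 25 patients;
500-trial comparison runs for the EWOC-versus-CRM overdose contrast) keep
each run to seconds while leaving the binomial standard errors of the
reported percentages near 1.5 points.

## Numerical choices and degenerate inputs

* Quadrature: trapezoid, 2001 nodes (1-D) and $201^2$ (EWOC), log-space
  likelihood accumulation; posterior normalization is exact by
  construction and checked to $10^{-6}$ in tests.
* Likelihood logs are formed family-aware ($\log\psi = e^a \log x$ for the
  empiric model) so 100-record histories at parameters $\pm 10$ keep finite
  log-likelihoods even where $\psi$ underflows.
* MLE search: golden-section (`optimize`) on $[-10, 10]$, tolerance
  $10^{-9}$, verified against an exhaustive grid with step $10^{-4}$.
* Ties in CRM selection break to the lower level within $10^{-10}$.
* Empty histories: likelihood 1, posterior = prior, recommendation = the
  design's starting level (the no-skip cap starts binding only after the
  first patient).
* Degenerate skeletons (non-increasing, boundary probabilities, $\delta$
  outside its range) are rejected at construction.

## Known limitations

Only the linear TITE weight is provided. One-parameter models are fitted by
quadrature, not MCMC; the EWOC grid bounds the MTD to the working-dose
range of the skeleton, so evidence that every level is too toxic
accumulates as mass at the lowest grid edge rather than below it. The
simulator is single-process by design (determinism over parallelism), and
the second stopping rule's fixed-level variant is provided but untested
against any published reference. Dose-combination (two-dimensional)
escalation, ordinal-toxicity models, model averaging and interval designs
such as mTPI/BOIN are out of scope.
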