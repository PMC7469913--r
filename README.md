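# crmdose

Model-guided dose-escalation designs for phase I cancer trials: conduct and
simulation of the continual reassessment method with Bayesian (CRMB) or
maximum-likelihood (CRML) estimation, the time-to-event CRM (TITE-CRM),
escalation with overdose control (EWOC), and time-to-event EWOC
(TITE-EWOC).

## The problem

A phase I oncology trial looks for the maximum tolerated dose (MTD): the
dose whose probability of dose-limiting toxicity (DLT) during the first
treatment cycle is closest to a prespecified target θ (typically 20–33%).
Algorithmic schemes such as 3+3 underuse the accumulating data; model-based
designs instead fit a parametric dose–toxicity curve after every patient
and treat the next patient at the dose the fitted curve recommends.

`crmdose` implements the ingredients of these designs as ordinary R
functions around a single classed fit:

* **Dose–toxicity models** — the empiric (power) model ψ(x, a) = x^exp(a),
  the one-parameter logistic with fixed intercept b,
  ψ(x, a) = logit⁻¹(b + eᵃ·x), and the two-parameter logistic used by
  EWOC, ψ(x, a₀, a₁) = logit⁻¹(a₀ + a₁x) with a₁ > 0.
* **Skeleton calibration** — prior DLT probabilities per level built by the
  indifference-interval construction: level ν is anchored at θ, and the
  parameter value that maps level i+1 to θ+δ maps level i to θ−δ.
* **Inference** — the (optionally weighted) binomial likelihood
  ∏ [wψ(xₗ,a)]^yₗ [1−wψ(xₗ,a)]^(1−yₗ); Bayesian posteriors by deterministic
  trapezoid quadrature in log space; maximum-likelihood estimation with the
  outcome-heterogeneity requirement; linear TITE weights w = u/T (1 on a
  DLT).
* **Dose selection** — CRM picks the level whose estimated DLT probability
  is closest to θ (ties to the safer level, no-skip escalation cap);
  EWOC picks the highest level whose posterior probability of exceeding
  the MTD, π(x) = P(MTD ≤ x | data), stays at or below the feasibility
  bound α, via a 2-D posterior on (ρ₀, γ) = (DLT probability at the lowest
  dose, MTD location).
* **Trial conduct** — a stateful trial object with inclusions, pending
  outcomes, follow-up updates, audited corrections, batch entry, JSON
  persistence and CSV export.
* **Simulation** — Monte-Carlo operating characteristics: distribution of
  the recommended MTD and per-level patient allocation under a true
  dose–toxicity scenario, with reproducible per-trial seed substreams.

## Worked example

Calibrate a six-level skeleton with target θ = 0.2, halfwidth δ = 0.05 and
the prior MTD at level 3, then fit a Bayesian CRM after four patients:

```r
library(crmdose)

sk <- calibrate_skeleton(theta = 0.2, delta = 0.05, nu = 3, K = 6)
sk
#> Skeleton on 6 levels (target theta = 0.2, prior MTD level 3)
#> level1 level2 level3 level4 level5 level6
#>  0.049  0.111  0.200  0.308  0.423  0.534

design <- crm_design("CRMB", sk,
                     stopping = list(stopping_rule("max_n", n = 25)))
h <- trial_history(dose_level = c(3, 4, 4, 5), outcome = c(0, 0, 0, 1))
fit <- crm_fit(design, h)
fit
#> CRMB fit: 4 patient(s), target theta = 0.2
#>          level1 level2 level3 level4 level5 level6
#> skeleton  0.049  0.111  0.200  0.308  0.423  0.534
#> estimate  0.071  0.122  0.192  0.278  0.375  0.474
#> Recommended next dose: level 3
#>   per-level estimates: 0.071 0.122 0.192 0.278 0.375 0.474
```

The skeleton row is the prior; the estimate row is the posterior-averaged
DLT probability per level after three non-DLTs (levels 3–4) and one DLT
(level 5). Level 3's estimate (0.192) is closest to the 0.2 target, so the
next patient is treated there. `coef(fit)` returns the posterior mean of
the model parameter (0.135 here), `predict(fit)` the per-level estimates,
and `plot(fit)` the prior and fitted curves.

Trial conduct wraps the same machinery statefully:

```r
tr <- trial_start(design, name = "demo")
tr <- include_patient(tr, outcome = 0)            # treated at start level 3
tr <- include_patient(tr, outcome = "pending", dose_level = 3)
tr <- update_pending(tr, id = 2, outcome = 0)
summary(tr)                                        # per patient / per dose
save_trial(tr, "demo.json")                        # audit trail included
```

A command-line interface (installed under `exec/crmdose`) exposes
`calibrate`, `init`, `include`, `update`, `modify`, `next-dose`, `summary`,
`export` and `simulate` subcommands over the same functions.

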