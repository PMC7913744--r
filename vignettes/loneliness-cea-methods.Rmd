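---
title: "Methods: a Markov cohort model of loneliness alleviation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a Markov cohort model of loneliness alleviation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lonelycea)
```

## The decision problem

Community "signposting" services connect lonely older people to local
social activities: a trained volunteer supports each client for roughly the
first 6 to 9 months, after which clients continue their chosen activities
at their own cost or drift away. Severe loneliness is associated with
higher incidence of several chronic conditions, more primary-care contact,
higher residential-care admission and elevated mortality, so alleviating
it may avert health and social care spending. `lonelycea` implements a
decision-analytic Markov cohort model that asks whether such a service is
worth its per-client cost when the outcome is measured in *loneliness-free
years* (LFY): a year not lonely counts 1, a year moderately lonely 0.5, a
year severely lonely (or dead) 0.

The model compares one cohort that receives the service against an
identical cohort that does not, over five annual cycles and four states:
not lonely, moderately lonely, severely lonely, dead. Everyone enters
lonely — 44% severely, 56% moderately, reflecting the eligibility
screening of the service the model emulates (four-item UCLA loneliness
scores of 10–12 and 7–9 respectively).

## Transition structure

All loneliness transitions are annual probabilities conditional on
surviving the cycle. The baseline death probability is 0.015 per year,
multiplied by a relative risk of 1.30 for the severely lonely only; the
printed loneliness flows are scaled by the survival probability and the
residual mass stays in the current state, which guarantees a row-stochastic
matrix for any admissible inputs (`transition_matrix()`).

The intervention arm's published transitions have a revealing mixture
structure: each one equals the no-intervention flow times (1 − e), plus an
exit to "not lonely" of roughly e, with e ≈ 0.191 — the published overall
probability of becoming not lonely after the intervention. In other words,
with probability e a participant escapes loneliness that year; otherwise
they churn exactly like an untreated person. This observation fixes two
otherwise arbitrary design choices below (the effectiveness lever and its
tornado behaviour).

### Engagement and dropout

Only engaged participants enjoy intervention dynamics. The model tracks
engagement explicitly with a seven-state expansion (engaged/disengaged
copies of the three alive states, plus dead; `intervention_matrix()`).
Disengaged survivors keep their current loneliness state and follow
no-intervention dynamics thereafter — dropouts retain nothing but what
they already achieved.

Sustained participation is 89% per year. Timing matters more than it
looks:

* During the supported phase of year one (taken as 7.5 months, the
  midpoint of the service's 6-to-9-month support window) nobody can
  meaningfully drop out.
* The annual dropout hazard therefore acts over only the remaining 4.5
  months of year one, giving a first-boundary retention of
  $0.89^{4.5/12} \approx 0.957$, and full annual retention of 0.89 at
  every boundary after that, applied after the cycle's transition.

This is the single most consequential timing convention in the model: it
moves the incremental LFY from 0.467 (no first-year dropout) or 0.430
(full first-year dropout) to 0.452, and the published downstream results
(the ICER and all its one-way variants) are mutually consistent only with
the intermediate value. The per-client intervention cost is likewise
charged once, in year one, for the 89% who sustain participation
(752 × 0.89 ≈ 669), undiscounted because first-year flows carry discount
exponent zero.

## Reward accrual and discounting

Outcomes and costs use differential discounting — 1.5% per year for
outcomes, 3.5% for costs — with discount exponent k − 1, so first-cycle
flows are undiscounted.

**LFY accrual is at cycle start**: cycle k rewards the occupancy entering
it. This reproduces the published per-arm LFYs (1.77 and 1.31) to printed
precision, whereas cycle-end accrual gives 1.85/1.29; no half-cycle
correction is applied. The accrual convention is an argument of
`loneliness_free_years()` so the alternative remains testable.

**Event costs are charged from cycle 2 onward**, also on cycle-start
occupancy. The interpretation: the elevated incidence of chronic illness
and service use attributable to a year of loneliness takes a model year to
manifest, so the entry-year mix generates no event costs. This convention
is strongly identified by the published cost table — the general-practice
category computes to 1467.4 against a printed 1467 (control arm), and the
depression category to 63.4 against 63; charging year one overshoots every
category by roughly a third.

Each event category is expected spending per person-year:
rate × unit cost × [occ(not) + occ(moderate) + RR × occ(severe)], with the
dead contributing nothing. The elevated risk applies to the severely
lonely only, except self-harm, whose relative risk (17.37) covers moderate
loneliness as well. Chronic conditions (coronary heart disease, stroke,
dementia, depression) are charged for the incidence year only: the model
has no illness states, so accumulating prevalence would invent structure
the four-state chain cannot support. Residential-care admissions are
costed as weekly cost × 52 in the admission year, with no carry-over, for
the same reason. These two simplifications are the main sources of
residual per-category discrepancy against the published cells (the stroke
cell especially), which is why the package's fidelity checks bind at the
level of totals, LFYs and ICERs rather than individual cells.

### The calibrated "other hospital contacts" category

The source table prices A&E attendances, ambulance call-outs and hospital
admissions but publishes no utilisation rate or relative risk for them,
while the results table reports one pooled "other hospital contacts" cell
per arm (799 / 818). `calibrate_other_contacts()` solves for the pooled
annual contact rate and its severe-loneliness relative risk so that the
category's discounted totals reproduce both cells exactly. Given the two
arms' occupancy traces the two cells are linear in the rate and monotone
in the relative risk, so the pair is identified; the solution
(rate ≈ 0.316 contacts/year at the admission unit cost, RR ≈ 1.37) is
found by root finding on the cell ratio and cross-checked in the test
suite against a grid-search oracle. Rate and unit cost enter only as a
product, so pricing the pooled contact at the admission tariff is a
labelling convention, not an assumption.

## Incremental analysis

`lonely_cea()` returns both arms' traces, cost breakdowns, LFYs and an
incremental result with dominance classification (`icer()`). At baseline:

```{r base}
fit <- lonely_cea()
fit
```

Currency is rounded only at the printing layer; all internal arithmetic is
unrounded (the published summary's own rounded cells do not reproduce its
ICER, so rounding there was presentational too).

## One-way sensitivity

`tornado()` perturbs one parameter at a time and reruns the pipeline,
restoring the base case between entries. The special id `"effectiveness"`
uses `scale_effectiveness()`, whose definition follows from the mixture
structure above: effectiveness is the achieved reduction in the relative
risk ρ = 1 − e of remaining lonely, and "x% less effective" multiplies ρ
by (1 + x). Scaling the factor therefore simultaneously shrinks the exit
flows and pushes every lonely-to-lonely flow back toward the control
dynamics — at 20% less effective the intervention has almost no effect
left (ICER ≈ 9100/LFY), while at 30% more effective it becomes dominant.
Simpler candidate levers (multiplying beneficial flows by the factor
directly) cannot reproduce this published collapse and were rejected;
the chosen definition reproduces the published ±10%/±20% ICER points.

```{r tornado, eval = FALSE}
tornado(loneliness_params(),
        ids = c("effectiveness", "costs.intervention_per_client",
                "rr.residential_care", "costs.residential_care_weekly"))
```

`discount_rate_variant()` reruns the model with outcomes discounted at the
cost rate (3.5%), the conventional equal-discounting check.

## Probabilistic sensitivity analysis

The source table assigns each parameter a distribution family — gamma for
costs, beta for probabilities, lognormal for relative risks — but no
dispersions. Every non-fixed parameter therefore defaults to a
coefficient of variation of 0.2, a common convention when standard errors
are unreported; it is configurable globally (`cv`) and per parameter
(`cv`/`se` columns). Consequences worth stating plainly:

* Deterministic results are unaffected.
* The *qualitative* probabilistic structure is robust: nearly all
  replications show the intervention more effective, mostly at extra cost,
  with a minority cost-saving; the acceptability curve rises through ~60%
  at a willingness to pay of £1000 per LFY and crosses 0.5 near the
  deterministic ICER.
* The *quantitative* percentages (the published 3.5% cost-saving share and
  the exact acceptability values) depend on the unknowable true
  dispersions and are treated as indicative, not binding; the tests check
  structure, ordering and a ±25% band on the break-even threshold.

Sampling (`sample_parameters()`) uses method-of-moments beta, shape/scale
gamma, and lognormal with the *arithmetic* mean pinned to the tabled value
(the table's point estimates drive the deterministic run, so the PSA
should be mean-consistent with it). Draws are clipped to admissible
bounds, the initial moderate share is tied to one minus the severe share,
and transition rows breaching their row-sum constraint are redrawn; clip
and redraw counts are reported in the result. The calibrated
other-contact drivers are sampled around their calibrated means like any
other parameter — the calibration is not re-run per draw.

`run_psa()` gives each replication its own L'Ecuyer-CMRG substream derived
from the master seed, so results are bit-reproducible, independent of
evaluation order, and a shorter run is a prefix of a longer one. The
fixture generator (`random_parameter_set()`) isolates its RNG from both
the global stream and the PSA streams.

## Degenerate inputs and numerical choices

* Ties at the willingness-to-pay threshold count as not cost-effective
  (strict inequality; measure-zero under continuous sampling).
* Zero incremental effect with positive incremental cost is labelled
  `dominated_by_convention` rather than producing an infinite ratio.
* Beta parameters with boundary means (0 or 1) are degenerate draws, not
  errors — the zero-valued control transitions and full-participation
  limits rely on this; means strictly outside [0, 1] are configuration
  errors.
* Row-stochasticity is enforced to 1e-12 at matrix construction and
  occupancy conservation verified to 1e-10 in the tests.
* The 95% plane ellipse is fitted by moments; a zero-variance cloud
  returns no ellipse with an explicit degenerate flag.

## What the synthetic parameter sets do and do not show

`random_parameter_set()` generates structurally valid (and deliberately
invalid) parameterisations: positive skewed costs, small incidence
probabilities, relative risks above 1, admissible transition rows. They
exercise every invariant of the engine — conservation, monotonicity,
additivity, perspective nesting — across the parameter space, and the
invalid modes pin the validator to the generator. They do not emulate
real-world parameter correlation (the analysis samples independently, as
the source analysis did) or individual-level heterogeneity; passing these
tests says the machinery is sound, not that any particular
parameterisation is realistic.

## Problem sizes

The packaged analyses are small by construction: the deterministic
pipeline is a handful of 4×4/7×7 matrix products and runs in microseconds;
the test suite uses 10,000-person microsimulations to cross-check the
cohort expectation, a few hundred Monte Carlo replications for convergence
checks and 3,000 for the probabilistic structure; the full published
analysis used 10,000 replications, which `run_psa()` executes in well
under a minute.

## Known limitations

* Chronic-condition and residential-care costs are incidence-year only
  (no prevalence accumulation, no carry-over), the acknowledged main gap
  against the published per-category cells.
* The volunteering wage is stored as printed (£0.21/hour) even though the
  table's own annotation names the national minimum wage (£8.21); the
  broader-perspective reproduction overrides it to 8.21, without which the
  published volunteering offset (−£10) cannot be reconstructed.
* No quality-of-life mapping: the effectiveness unit is the bespoke
  loneliness-free year, not a QALY.
* No expected-value-of-information analysis, and no correlated parameter
  sampling.
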