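# lonelycea

A decision-analytic Markov cohort model of the cost-effectiveness of a
loneliness-alleviation service for community-dwelling people aged 65 and
over in England, evaluated against no intervention. The package is for
health economists and public-health analysts who want the published
analysis as runnable, testable code — to reproduce it, perturb it, or
re-parameterise it for another setting.

## The model

Four states — not lonely, moderately lonely, severely lonely, dead — over
five annual cycles. Everyone enters lonely (44% severely, 56%
moderately). The intervention raises the chance of escaping loneliness
(the published transitions are a mixture: exit to "not lonely" with
probability *e* ≈ 0.19, otherwise churn like an untreated person);
participants sustain engagement with probability 0.89 per year after the
6–9-month supported phase, and dropouts revert to no-intervention
dynamics. Severe loneliness raises the risk of death (RR 1.30) and of
costed events — GP contact (RR 1.86), depression (1.23), self-harm
(17.37, also for moderate loneliness), coronary heart disease (1.29),
stroke (1.32), dementia (1.58), residential-care admission (2.13) — each
valued at 2019 NHS/PSSRU unit costs.

Effectiveness is measured in loneliness-free years (LFY): a cycle weighs
1 if not lonely, 0.5 if moderately lonely, 0 otherwise. Outcomes are
discounted at 1.5% per year, costs at 3.5%. The headline statistic is the
incremental cost-effectiveness ratio

ICER = (C_int − C_ctl) / (E_int − E_ctl)  [GBP per LFY gained],

with dominance handled explicitly. One-way (tornado) sensitivity
analysis, probabilistic sensitivity analysis (10,000 Monte Carlo
replications over beta/gamma/lognormal parameter distributions),
cost-effectiveness acceptability curves, and a broader-perspective
scenario (informal care for stroke and dementia, minus the value of
participants' own volunteering) are included. Modelling conventions and
their justification are documented in
`vignettes/loneliness-cea-methods.Rmd`.

## Worked example

```r
library(lonelycea)

fit <- lonely_cea()          # packaged baseline, health & social care perspective
fit
#> Loneliness-alleviation cohort model (health_social_care perspective, 5 cycles)
#>   total cost:       7216 vs    6870 GBP (delta +345)
#>   LFY:              1.77 vs    1.31     (delta +0.45)
#>   ICER:              764 GBP per loneliness-free year
```

Participation costs £669 per client (752 × 89% uptake) and averts roughly
£324 of care costs over five years, so the service is not cost-saving; it
buys 0.45 loneliness-free years at £764 each. The per-category breakdown:

```r
summary(fit)
#> Cost-effectiveness summary (health_social_care perspective)
#>                 category intervention control
#>             intervention          669       0
#>                gp_visits         1400    1467
#>               depression           62      63
#>                self_harm           46      55
#>                      chd           70      72
#>                   stroke          104     107
#>                 dementia          663     686
#>         residential_care         3402    3603
#>  other_hospital_contacts          799     818
#>               total_cost         7216    6870
#>                      lfy         1.77    1.31
#> ICER: 764 GBP per loneliness-free year
```

Sensitivity analyses:

```r
# 10% less effective intervention: ICER rises sharply
lonely_cea(scale_effectiveness(loneliness_params(), 0.9))$result$icer
#> [1] 1858.67

# parameter uncertainty: 10,000 replications, seeded
psa <- run_psa(loneliness_params(), n = 10000, seed = 1)
psa$break_even                       # WTP where acceptability crosses 50%
plot(psa)                            # CE plane + acceptability curve
```

User parameter sets load from JSON/YAML/CSV (`read_params()`,
`write_params()`); `tornado()`, `discount_rate_variant()` and
`lonely_cea(..., "broader")` cover the remaining published analyses, and
`export_cea()` / `export_psa()` write CSV outputs with a run manifest.

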