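# mhsd — regional mental-health system dynamics

`mhsd` is an R package for planners and modellers who need to compare
suicide-prevention investment strategies at the scale of a regional health
system. It implements a deterministic stock-and-flow system dynamics model
of psychological distress, mental-health service pathways and suicidal
behaviour for a two-district region (a large and a small health district
composing one primary-care region), together with the machinery that turns
the simulator into a decision tool: an intervention catalogue, exhaustive
multi-objective scenario search with Pareto filtering, derivative-free
calibration, and Latin-hypercube sensitivity analysis.

## The model

The population moves between 11 stocks: *well* (low/no distress, K10 ≤ 15),
*distressed not in care* (K10 ≥ 16), two service queues (awaiting GP,
awaiting psychiatrist/allied specialist), five care states (GP care,
specialist care, community mental healthcare, psychiatric inpatient, online
services), *disengaged* and *post-attempt*. Flows follow an explicit Euler
scheme on a 1/16-week grid (0.4375 days; one model year = 52 weeks):

- distress onset `well → distressed` at rate `μ·s(t)`, where `s(t)` is a
  rectangular pandemic pulse on distress onset from March 2020;
- help seeking into the GP queue; service intakes capped by weekly
  capacities that compound at service-specific annual growth rates;
- queue waits by Little's law (`wait = queue / throughput`, capped), with
  disengagement from queues at rate `δ₀ + δ₁·wait` — longer waits push more
  people out of care;
- suicide attempts at state-specific hazards (untreated > in-care;
  post-attempt highest), with fixed case-fatality and hospitalised
  fractions feeding the suicide-death and self-harm-hospitalisation
  counters; attempts and a share of crisis contacts present to emergency
  departments;
- proportional outflow rationing guarantees stocks never go negative, and
  persons are conserved exactly up to demography and suicide deaths.

Three cumulative outcomes are minimised over an evaluation window
(2021–2031 by default): suicide deaths, mental health-related ED
presentations, and disengagements from care.

Twelve interventions can be switched on from 2021: eight programs
(post-attempt assertive aftercare, GP training, community education, family
psychoeducation, safety planning, safe spaces, social connectedness,
community-based acute care) and four capacity levers (GP,
psychiatrist/allied, inpatient, CMHC). Effects are declared in an editable
JSON catalogue and combine multiplicatively on shared parameters.
Aftercare is delivered through existing community mental healthcare, so it
*consumes* CMHC capacity in proportion to enrolment — the structural source
of the trade-off between minimising suicides and minimising disengagement.

Free parameters are calibrated to six historical series (distress
prevalence, self-harm hospitalisation and suicide rates, GP and
specialist service volumes, bed occupancy) by minimising the sum of
per-series mean absolute percent errors (MAPE) with Powell's
conjugate-direction method under box constraints.

Because the original regional datasets are confidential, the package ships
a synthetic-data generator that reproduces the region's published headline
statistics (total population 1,269,782; distress prevalence 13.5 per 100;
suicide rate 13.7 per 100,000/yr; burden split ≈ 73.5% / 26.5% between the
two districts) and emits noisy annual "historical" series for calibration
tests.

## Worked example

```r
library(mhsd)

configs <- profile_configs()                 # two synthetic districts
traj <- simulate_region(configs$hunter_new_england, t_end = 28)
cumulative_outcomes(traj, c(10, 20))         # decade 2021-2031
#>   scenario_id region_id   window_start window_end suicides ed_presentations
#> 1 baseline    hunter_new_…           10         20    1456.          135212.

sets <- enumerate_sets(intervention_catalogue(), 4)   # all 495 combinations
tab <- evaluate_scenarios(configs, sets = sets[c(31, 126, 283, 460), ],
                          window = c(10, 20), dt = 1/104)
front <- pareto_front(tab, region = "PHN")
front
#> <mhsd_pareto> 1 non-dominated of 4 scenarios
#>   (suicides, ed_presentations, disengagements; minimise)
outcome_report(tab, front)
#>   label scenario_id                                     suicides pct_suicides
#> 1 a     cap_specialist+safe_space+safety_planning+...      1820.          8.9
#> 2 0     baseline                                           1997.          0
```

The report rows give the three outcome counts over the window and percent
reductions against business as usual, rounded to one decimal and always
recomputable from the counts. `pareto_front()` keeps every scenario not
weakly beaten on all three outcomes (and strictly on one) by any other;
`best_per_outcome()` returns the argmin per outcome; `lhs_design()` +
`run_sensitivity()` + `summarise_draws()` propagate ±20% effect-size and
±50% shock-duration uncertainty into interval summaries;
`calibrate_model()` fits free parameters to `calibration_targets()` data.
`run_pipeline(seed)` chains the whole analysis.

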