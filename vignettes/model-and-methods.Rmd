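---
title: "Model structure, calibration and scenario analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, calibration and scenario analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mhsd)
```

`mhsd` simulates how psychological distress, mental-health service
pathways and suicidal behaviour evolve together in a regional health
system, and compares combinations of prevention programs and
service-capacity investments across three outcomes at once. This vignette
documents the model, its assumptions and defaults, the numerical choices,
and what the synthetic data generator does and does not emulate.

## The stock-flow model

The modelled population of a district occupies 11 mutually exclusive
stocks. One stock holds people with low or no psychological distress
(Kessler-10 score 15 or below); everyone else is in the moderate-to-very
high distress band (K10 of 16 or over), distributed across: distressed not
in care, two waiting queues (GP, psychiatrist/allied specialist), five
care states (GP care, specialist care, community mental healthcare [CMHC],
psychiatric inpatient, online services), a disengaged stock and a
post-attempt stock. The K10 instrument leaves a score of exactly 15
between the two published band definitions; we assign it to the well band,
the conventional cut for "moderate and above" being 16+.

Flows, all first-order in the originating stock:

* **Onset and recovery.** Onset `well → distressed` at rate μ (default
  0.140/yr), multiplied by a rectangular pandemic pulse (below); untreated
  recovery at ρ (0.50/yr). Defaults were set by flow balance so the
  distress-band equilibrium sits near the 13.5-per-100 prevalence the
  generator targets.
* **Help seeking and the service cascade.** Distressed people enter the GP
  queue at rate h (1.30/yr). Service intake per unit time is
  `min(queue/dt, capacity)`; weekly capacities compound at per-service
  annual growth rates. GP episodes complete at 4/yr and split: 50%
  recover, 20% referred to the specialist queue, 10% to CMHC, 10% to
  online services, 10% unresolved (back to distressed, eligible to
  re-seek). Specialist and CMHC episodes complete at 3/yr (75% and 70%
  success), online at 8/yr (50%). The split fractions deliberately leave
  headroom below 1 so program effects on referral and success fractions
  remain valid without renormalisation in typical combinations;
  combinations that would push the sum past 1 are rescaled with a warning.
* **Queueing and disengagement.** Waits follow Little's law
  (queue/throughput, in weeks, capped at 52). People leave queues and care
  at a base disengagement rate δ₀ = 0.85/yr plus δ₁ = 0.05/yr per week of
  wait; disengagers accumulate in the disengaged stock and re-engage at
  0.60/yr or recover untreated. Every disengagement event increments the
  third outcome counter.
* **Suicidal behaviour.** Attempts arise at state-specific hazards:
  untreated states (distressed, queues, disengaged) 0.0095/yr, in-care
  states 0.006/yr (the model assumes care is protective, so the in-care
  hazard may not exceed the untreated one), post-attempt 0.25/yr. A fixed
  case fatality (0.11) yields suicide deaths; of survivors a fixed
  fraction (0.85) is hospitalised — the self-harm proxy series — and
  admitted to the inpatient stock while beds allow, with overflow and
  non-hospitalised survivors entering post-attempt follow-up. Hospitalised
  counts are admission events and accrue even when bed capacity defers the
  inpatient transition. Post-attempt clients exit at 4/yr, 40% linked into
  CMHC care (capacity permitting), the rest returning to the distressed
  pool.
* **Emergency department presentations.** All attempts present to an ED;
  crisis presentations additionally arise from untreated states at
  0.11/yr. Diversion programs (safe spaces, community acute care) remove
  their share of crisis contacts from the counter before counting; the
  acute-care share also transitions into CMHC care when capacity allows.
  Diverted contacts never count as ED presentations even when the care
  transition is capacity-blocked — the crisis response still happened
  outside the ED.
* **Demography.** Entries (births/maturation plus net migration) join the
  well stock; background mortality removes from every stock. Person
  conservation — the total changes exactly by demography minus suicide
  deaths — is asserted per step in the tests.

### The pandemic shock

Only distress onset is shocked: a rectangular pulse multiplies μ from
1 March 2020 for 2.0 years. The multiplier default (1.10) was set so the
simulated baseline suicides-per-year series rises by about 6% from early
2020 to late 2021, the qualitative shape the model family is built to
reproduce; the simulated rise at that default is 6.1%. Varying the
duration (as the sensitivity analysis does, ±50%) moves only the pulse
end, never its height.

## Interventions

The catalogue (`inst/extdata/interventions.json`) declares 12 entries:
8 programs and 4 capacity levers. Mechanisms are structural; the effect
*magnitudes* are editable, literature-anchored placeholders (e.g. a 0.8
re-attempt hazard ratio for assertive aftercare and for safety planning, a
1.25 referral multiplier for GP training), and every test that depends on
magnitudes uses synthetic ground truth rather than these defaults.

Design choices:

* Effects combine multiplicatively on shared rate parameters (adds on the
  additive channels), which preserves positivity and makes application
  order-irrelevant; clamping keeps every fraction inside its declared
  bounds. Non-additivity between interventions emerges structurally
  through shared capacity, not through bespoke interaction terms.
* Rollout is instantaneous at 1 January 2021 at full scale.
* Aftercare consumes CMHC capacity at 0.1 services per enrolled
  post-attempt client per week. This is the engine of the trade-off
  between suicide-minimising and disengagement-minimising portfolios:
  intensive post-attempt support crowds out CMHC throughput, queues and
  waits grow, disengagement rises.
* Community education's help-seeking effect scales with a community
  support factor, linear in social-connectedness coverage
  (`1 + 0.5 × coverage`, so 1 with no connectedness program, 1.5 at full
  coverage).
* Capacity levers multiply the annual growth rate of GP, specialist and
  inpatient capacity (default multiplier 2 when switched on), except the
  CMHC lever, which adds an absolute annual increment in contacts per
  10,000 population per week (default 0.15 when on; its business-as-usual
  value is 0, i.e. no CMHC growth).

## Calibration

Free parameters are fitted by minimising the sum over six series of the
mean absolute percent error between observed and simulated values
(`100/n · Σ|obs − sim|/|obs|`), each series sampled at its observed
timestamps (trailing 12-month totals for rates and volumes, interpolated
stocks otherwise). The optimiser is a hand-implemented Powell
conjugate-direction search: repeated Brent line minimisations along a
direction set with the classical replacement rule, run in box-normalised
coordinates with line searches clipped to the feasible segment, so bounds
hold exactly and accepted iterates are monotone. Simulation failures
return a large finite penalty so the search can continue. Defaults:
`xtol = 1e-4` (normalised), `ftol = 1e-6`, 200 iterations, plus seeded
jittered restarts (best kept).

The default free set contains six parameters chosen so each has a
dedicated signal: distress onset (prevalence), help seeking (GP volumes),
GP→specialist referral (allied volumes), untreated attempt hazard (suicide
rate), hospitalised fraction (self-harm rate), inpatient discharge (bed
occupancy). Untreated recovery and case fatality stay fixed: with them
free the objective develops flat ridges (only the products
case-fatality × hazard and survival × hospitalised-fraction × hazard enter
the attempt-chain series), and no optimiser can recover what the data do
not identify. On noiseless synthetic histories the refit returns to the
generating values essentially exactly; with 5% observation noise,
parameter errors stay within the mid-teens of a percent, dominated by the
noise floor of seven annual observations per series.

## Scenario search and Pareto filtering

All `C(12, k)` unordered intervention subsets (495 at the default k = 4)
are simulated per district over 2021–2031, against a shared
business-as-usual warm-up to 2021. Outcomes are cumulative counts over the
window; regional (PHN) results are component-wise sums of the districts.
Dominance is the standard weak/strict pair under minimisation: scenario A
dominates B if A is no worse on all three outcomes and strictly better on
at least one; ties (identical triplets) are mutually non-dominating and
all retained. The front implementation scans rows in lexicographic order
against the running front (a dominator always precedes what it dominates
in that order, and dominance is transitive); the tests verify it against a
brute-force all-pairs oracle on random instances. Best-per-outcome
selection breaks ties lexicographically by scenario id. Report labels
(a, b, c, ...) are assigned by descending suicide reduction.

## Sensitivity analysis

Latin hypercube sampling draws 100 parameter sets by default: one
dimension per program effect scale (uniform on ±20% of the default
deviation from no-effect) and one for the pandemic-shock duration (±50%).
Capacity levers are policy settings, not uncertain effects, and are not
varied. Within-stratum sampling is uniform — the natural maximum-entropy
choice on a bounded range. Each draw re-runs baseline and scenarios;
percent reductions are summarised by mean and 50%/95% empirical intervals
using the linear-interpolation quantile rule (type 7), so interval checks
in the tests are exact. These intervals measure the impact of assumed
effect-size uncertainty; they are not confidence intervals.

## Synthetic data

`default_profiles()` defines two districts splitting a total population of
1,269,782 at burden shares 1307/1778 and 471/1778, with distress
prevalence 13.5 per 100 and a suicide rate of 13.7 per 100,000/yr — the
published headline statistics of the region the model family targets.
Weekly service capacities (2,250 GP consultations, 450 specialist
services, 26 admissions, 240 CMHC contacts region-wide, split by share)
were set by flow balance so baseline utilisation is high but feasible:
GP slightly slack, specialist and CMHC near-binding, inpatient below its
cap. `generate_history()` simulates the truth parameters over 2011–2018,
samples the six calibration series at annual timestamps (the cadence of
the public collections these series mirror) and applies mean-one
multiplicative lognormal noise, so generated values stay positive and
MAPE denominators are safe.

What the generator does **not** emulate: age/sex structure, seasonality,
reporting artefacts (suicide misclassification, self-harm
under-enumeration), cross-district patient flow, and any microstructure of
the confidential regional datasets. Passing the recovery tests shows the
estimation machinery is correct and identifiable under the model's own
assumptions — not that the model family or its defaults are correct for
any particular real region.

## Numerical choices

* Explicit Euler at `dt = 0.4375` days (1/16 week), the convention of the
  system-dynamics tools this model class is usually built in; one model
  year is 52 weeks, so the grid divides the year exactly (832 steps/yr,
  23,296 steps over 28 years). Halving the step changes decade outcomes
  by about 0.1%, comfortably inside the 1% tolerance the tests assert.
* Proportional outflow rationing: when a stock's proposed outflows exceed
  its content within a step, all its outflows scale by the same factor.
  This prevents negativity without privileging any flow; the post-attempt
  stock's attempt departure is bounded by its worst case so the guarantee
  holds there too.
* CMHC intake priority when capacity binds: post-attempt linkage first,
  GP referrals second, acute-care diversions last; blocked linkage and
  referrals return to the distressed pool, blocked diversions stay put.
* Calibration simulations run at a half-week step for speed (the same
  step used to generate targets, keeping the noiseless refit objective
  exactly zero at truth); reporting runs use the full grid.
* Degenerate inputs: zero-throughput queues report the wait cap and a
  saturation flag; zero completion rates seed zero occupancy in the
  initial state; MAPE refuses zero observed values by name.

## Problem sizes in the shipped tests

The test suite runs the full 28-year, 23,296-step engine checks, a
300-instance randomised Pareto oracle comparison (1,000 instances in the
acceptance tests), six-parameter noiseless and noisy recovery fits, and a
20-draw scenario sensitivity propagation; the end-to-end pipeline example
uses k = 2 portfolios and 3 draws. These sizes were chosen so the whole
suite documents the claimed properties in about a minute of compute while
the acceptance script re-runs the full 495-scenario search.

## Known limitations

Aggregate, deterministic dynamics only — no demographic stratification, no
stochastic small-count behaviour (relevant for the smaller district's
suicide counts), no economic costing, no staged rollouts or budget
constraints. The service-pathway branching is one concrete structure
consistent with the model family's published outline; alternative
branchings can be expressed by editing `model_params()` fractions and the
catalogue, but structural changes (new stocks) require extending the
engine. Intervention effect magnitudes are placeholders pending real
evidence synthesis: conclusions about *which* portfolio is optimal should
be drawn only after calibrating to real regional data and reviewing the
catalogue's effect sizes.
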