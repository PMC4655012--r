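---
title: "An agent-based model of a metropolitan SPMI care ecosystem"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An agent-based model of a metropolitan SPMI care ecosystem}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spmiecosim)
```

## The model

`spmiecosim` simulates, week by week, a cohort of people with serious and
persistent mental illness (SPMI) moving through a metropolitan ecosystem of
medical, social and criminal-justice services. Every patient is an agent
with:

* a **mental-health score** on 1--100 (approximating the Global Assessment
  of Functioning scale) with a per-patient **floor** -- untreated patients
  decline to a certain level and no further -- and a **physical-health
  score** on the same scale; the two scores pull weakly on each other;
* a **medication-adherence state chart**: the patient is on or off their
  prescribed medicine, and transitions are driven by a signed factor score
  (stress and active substance abuse and side-effect burden and cost push
  down; family support, an active long-acting injectable (LAI) depot and
  recent provider contact push up), with hysteresis between the stop and
  start thresholds;
* a **treatment plan** (medicine, community mental-health-centre and
  case-worker appointment schedule);
* a **physical environment** -- private residence, assisted living,
  homelessness, hospital inpatient, correctional facility -- with weekly
  score effects, costs, and a probability that an outreach effort can
  locate the patient there;
* **finances** (employment, benefits, patient-borne costs) that modulate
  access to services through a 0--5 cost-to-patient factor;
* a **criminal history** and, possibly, a place on the jail or jail
  diversion roster.

Each simulated week applies a fixed decision sequence per patient:
critical outcomes first (crisis onset, the separate crime channel,
substance-abuse and employment changes -- highest priority applies), then
crisis resolution (hospitalization, arrest, homelessness, suicide, or
stabilization at a crisis stabilization unit, drawn from a configured
mix), the adherence step, appointment attendance against capacity-limited
providers, the refill decision, environment length-of-stay countdowns and
transitions, the two score updates, and finances. Patients are processed
in a freshly shuffled order each week because providers' weekly capacity
is shared. All state-changing arithmetic lives twice, deliberately: a
readable single-patient reference implementation in R
(`weekly_update()` and the operations it composes) and a compiled
population engine (`run_simulation()`); tests hold the two in exact
agreement on deterministic configurations.

### Care coordination: the two levers

The model's purpose is to quantify care-coordination technology through
two levers:

* **Handoff success rate.** Every inter-provider transfer -- a hospital
  discharge, a jail release, a routine plan transfer between providers --
  retains the patient with probability
  `handoff_success_rate x probability_of_being_located(environment)`.
  On failure the patient is *lost to the system*: no appointments, no
  refills, declining scores, until a later crisis resolution re-engages
  them (with a renewed plan and prescription), again subject to the
  handoff.
* **Appointment compliance rate.** A scheduled appointment is attended
  with probability `compliance x access_factor(cost factor, resources)`,
  capacity permitting. Attendance provides contact (feeding the adherence
  chart and the mental-health update), the provider's per-visit effect,
  and -- crucially for continuity -- re-injection of LAI depots, which
  otherwise lapse after their interval.

## The shipped calibrated profile

No parameter values for a real city are available for this class of model;
the package therefore ships `default_profile.yaml`, a complete,
repo-authored "calibrated city" of ~1,000 tracked patients over 260 weeks
(5 years), tuned by the package's own calibration loop so that headline
outputs sit at plausible magnitudes: roughly 1,000 crises per year, ~300
hospital admissions, ~320 arrests, a realized appointment-attendance rate
around 42% (the stylized fact is that attendance is below one half), and
a bimodal severity distribution in which disengaged patients sink toward
their floors while engaged patients stabilise high. Costs use an abstract
currency; all reported cost results are percent changes against baseline,
which is scale-free.

Parameters worth knowing (all per week unless suffixed):

| parameter | default | meaning |
|---|---|---|
| `levers.handoff_success_rate` | 0.15 | baseline transfer retention; deliberately poor -- losing track of patients is the problem the technology addresses |
| `levers.patient_appointment_compliance_rate` | 0.45 | baseline show-up probability |
| `patients.plan_transfer_weekly` | 0.006 | routine inter-provider transfer rate (step-down care, provider turnover) |
| `patients.crisis_onset_weekly` | 0.045 / 0.02 / 0.006 / 0.0012 | weekly crisis probability by coarse severity band |
| `patients.crisis_outcomes` | 0.34 / 0.196 / 0.04 / 0.004 / 0.42 | hospitalization / arrest / homelessness / suicide / stabilized |
| `adherence_chart.stop / start` | -0.55 / 0.05 | hysteresis thresholds on the factor score |
| `medicines.lai_sga.refill_frequency_weeks` | 12 | depot interval; lapses without re-injection at an attended contact |

The coarse severity bands group the GAF-style deciles as severe (1--30),
serious (31--50), moderate (51--70) and mild (71--100); decile banding is
available through `mh_category()`.

## Calibration

`calibrate()` reproduces the tiered procedure: tier 1 matches a single
high-confidence headline statistic (total crises per year, reference
1,000, tolerance +/-20%), tier 2 the crisis-outcome levels
(hospitalizations, arrests, homelessness entries, suicides), tier 3 the
drivers (adherence rate, living-arrangement distribution). The search is
coordinate descent with a golden-section line search per parameter,
objective = maximum relative error over the current tier's metrics *plus
all earlier tiers'* (adjusting an input rarely moves only one metric), on
replication means under common random numbers. The reference values in
`calibration_targets.yaml` are synthetic, repo-chosen magnitudes -- they
define the operating point, they are not measurements of any city.
`variability_check()` covers the internal-dynamics check: the temporal
standard deviation of each patient class's mean mental-health score, where
classes are the coarse band of the initial score; frozen dynamics give
exactly zero.

## The intervention experiments

`run_sweep()` shifts one lever in 1-percentage-point steps (handoff -15 to
+20, compliance -10 to +20; shifted rates clamp to [0,1]) and runs paired
replications per point -- the i-th replicate of every delta shares a seed,
so contrasts against the delta = 0 baseline are common-random-number
paired. `handoff_outcomes()` and `compliance_outcomes()` then summarise
the expert-panel bands (+5..+15 handoff points; +3..+12 compliance
points) as the min and max over deltas of the reported measures.

Problem sizes: the sweeps in the package's acceptance script and tests
use the full grids at 1,000 patients x 260 weeks with 100 paired
replications per delta point. The general-purpose default is 30
replications; the band summaries, however, are extrema over 10--16 delta
points, and at 30 replications the sampling noise of each point
(~0.3--0.4 points of the private-residence measure) biases a band minimum
down and a maximum up by a comparable amount -- more replications is
variance reduction of the same estimand.

### What the calibrated profile achieves, and what it does not

With the shipped profile the handoff lever's responses have the right
sign, ordering and low-end magnitudes: improving handoff by +5 points
raises the medicated share by ~3 percentage points and cuts incarceration
cost by ~6%, with hospitalization reductions consistently *below*
incarceration reductions (the criminal-justice system, not the hospital,
is where lost patients surface -- bed capacity also absorbs part of the
hospital-demand change). Two features are **not** reproduced and are left
honestly out of band:

* The top of the target bands implies a strongly saturating response
  (improvement at +15 only ~1.6x the improvement at +5). In this
  reconstruction the lost-patient pool is a smooth birth-death process
  whose band-edge ratio is ~2.5 for every mechanism variant we examined
  (re-engagement staging, crisis-service congestion feedback,
  locate-probability heterogeneity, depot-continuity effects); the +15
  responses therefore overshoot the printed maxima.
* The compliance lever's crisis-cost reductions at the low end (+3
  points) are ~0.5--0.9% here against the band's lower edge of 1%; the
  joint requirement with the +12 upper edge (3%) leaves no tuning room in
  this model.

Both gaps are properties of the reconstructed dynamics, not of the
estimator; they are documented rather than forced.

## Synthetic population: what it emulates and what it does not

`synthesize_population()` draws every initial characteristic
independently from the configured marginals (severity, floors, physical
health, trait stress, family support, finances, substance abuse,
employment, plans, environments, criminal history), with one enforced
dependence: the mental-health floor is clipped to lie at or below the
initial score. Real cohorts correlate these fields (severity with
homelessness, substance abuse with justice involvement); passing tests on
this generator therefore demonstrates internal consistency of the
mechanics and calibrated aggregates, not predictive validity for any real
city. There is no household structure, no migration in or out of the
cohort, and mortality occurs only through crisis suicide.

## Numerical choices and degenerate inputs

* Scores clamp to `[floor, 100]` and `[1, 100]`; clamping is idempotent.
* Adherence thresholds use strict inequalities; a score exactly at a
  threshold does not transition.
* The admission week of an episodic stay does not count against the
  length of stay; stays are `min + Poisson(mean - min)` weeks.
* A full assisted-living facility overflows to homelessness; a hospital
  that cannot admit resolves the crisis as a stabilization; a crisis
  stabilization unit at capacity yields an unresolved crisis (score shock
  only).
* A `run_length_weeks` of zero returns an empty series with the initial
  summary; an empty population is permitted.
* All randomness flows from R's RNG: `(profile, seed)` reproduces runs
  bit for bit, in the compiled engine and the R reference alike.

## A worked example

```{r example, eval = FALSE}
cfg <- load_default_profile()
r <- run_simulation(cfg, seed = 1)
r
#> <spmi_run_result> 1000 patients x 260 weeks (seed 1 )
#>   annual crises 1028.0 | hospitalizations 308.6 | arrests 340.8 | suicides 4.00
#>   on medication 52.9% | lost to system 48.9% | attendance 41.8%
#>   total cost 68086443 (incarceration 15610100, hospitalization 7457670)

res <- calibrate(cfg, n_reps = 4, budget = 24)
res$achieved[res$achieved$tier == 1, ]

sw <- run_sweep(sweep_spec("handoff", cfg = cfg, replications = 30))
handoff_outcomes(sw, band = c(5, 15))
```

## Limitations

* Parameters are synthetic; nothing here should be read as a statement
  about a particular metropolitan area.
* The weekly tick hides intra-week ordering; at most one critical outcome
  fires per patient-week.
* The decision order within a week is fixed and documented; changing it
  changes results and is treated as a breaking change of the profile
  schema version.
* Medication is modelled at the level of refill interval, depot flag and
  side-effect severities only.
* Whether "untreated" means off-medication, out of contact, or both is
  ambiguous in the source material; here decline applies only when the
  patient is off medication *and* had no provider contact that week.
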