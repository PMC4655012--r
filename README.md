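# spmiecosim

Agent-based weekly microsimulation of a metropolitan care ecosystem for
people with **serious and persistent mental illness (SPMI)** — the medical,
social and criminal-justice services they move through, and the effect of
**care-coordination technology** on that system.

Every patient is an agent with a mental-health score on 1–100
(approximating the Global Assessment of Functioning scale, with a
per-patient floor that untreated decline cannot cross), a physical-health
score, a medication-adherence state chart driven by a signed factor score
(stress −, substance abuse −, side-effect burden −, cost −, family
support +, active long-acting injectable +, recent provider contact +),
a treatment plan, finances, a physical environment (private residence,
assisted living, homeless, hospital inpatient, correctional facility) and
a criminal history. Each simulated week applies a fixed decision sequence:
critical outcomes (crisis, crime, substance abuse, employment) → crisis
resolution (hospitalization / arrest / homelessness / suicide /
stabilization) → adherence → appointments against capacity-limited
providers → refills → environment transitions → score updates → finances.

Two system levers model care coordination:

* **Handoff Success Rate** — the probability that a patient referred or
  discharged between providers is retained rather than *lost to the
  system* (no appointments, no refills, declining scores, until a later
  crisis re-engages them);
* **Patient Appointment Compliance Rate** — the probability a scheduled
  appointment is attended.

The package ships a fully specified synthetic "calibrated city" profile
(~1,000 patients, 5 years = 260 weekly ticks), a tiered calibration
routine that tunes profile parameters to aggregate reference targets
(crisis counts first, then crisis-outcome levels, then drivers), and the
two care-coordination intervention experiments: 1-point lever sweeps
(handoff −15..+20, compliance −10..+20) with paired-seed replications and
expert-panel band summaries.

## A worked example

```r
library(spmiecosim)
cfg <- load_default_profile()
r <- run_simulation(cfg, seed = 1)
r
#> <spmi_run_result> 1000 patients x 260 weeks (seed 1 )
#>   annual crises 1028.0 | hospitalizations 308.6 | arrests 340.8 | suicides 4.00
#>   on medication 52.9% | lost to system 48.9% | attendance 41.8%
#>   total cost 68086443 (incarceration 15610100, hospitalization 7457670)
```

The summary line reads: about 1,028 mental-health crises per simulated
year across the 1,000-patient cohort, of which ~309 end in a hospital
admission and ~341 in an arrest; on an average week 52.9% of living
patients are taking their medication while 48.9% are disengaged from care
after a failed handoff; 41.8% of scheduled appointments are kept (the
baseline stylized fact is that attendance is below one half); and
incarceration dominates hospitalization in the five-year cost ledger
(abstract currency — analyses report percent changes, which are
scale-free).

Sweeping the handoff lever and summarizing the expert-panel band:

```r
sw <- run_sweep(sweep_spec("handoff", cfg = cfg, replications = 30))
handoff_outcomes(sw, band = c(5, 15))
#>                              measure  min   max
#> 1       on_medication_improvement_pp 2.87  8.49
#> 2   incarceration_cost_reduction_pct 4.73 15.82
#> 3 hospitalization_cost_reduction_pct 3.22 12.38
```

Improving the handoff rate by 5–15 percentage points raises the medicated
share of the population by roughly 3–8 percentage points and cuts
five-year incarceration cost by roughly 5–16%, with hospitalization-cost
reductions consistently below the incarceration ones — lost patients
surface in the criminal-justice system more than in the hospital.

A command-line front end is provided at `inst/cli/spmi-ecosim`
(`validate`, `run`, `sweep`, `calibrate` subcommands).

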