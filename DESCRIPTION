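Package: spmiecosim
Title: Agent-Based Simulation of a Metropolitan Mental Health Care Ecosystem
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level weekly microsimulation of a metropolitan care
    ecosystem for people with serious and persistent mental illness (SPMI).
    Each patient agent carries mental- and physical-health scores (1-100, the
    mental score approximating the Global Assessment of Functioning scale), a
    medication-adherence state chart, a treatment plan, finances, a physical
    environment and a criminal-justice history, and is updated every simulated
    week through a fixed decision sequence: critical outcomes (crisis,
    substance abuse, employment), crisis resolution, adherence, appointments
    against capacity-limited providers, refills, environment transitions,
    score updates and finances. The package ships a calibrated default city
    profile, a tiered calibration routine that tunes profile parameters to
    aggregate reference targets, and parameter-sweep experiments for two
    care-coordination levers (referral handoff success and patient appointment
    compliance) with cost and outcome summaries.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tools,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
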