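# Calibration reference targets for the shipped default city profile.
#
# SYNTHETIC REFERENCES: every reference value below is repo-chosen -- a
# plausible magnitude for a tracked metropolitan SPMI cohort of ~1,000
# patients -- not taken from any published city dataset. They define the
# aggregate operating point the default profile is tuned to.
#
# Tier 1 matches the single high-confidence headline statistic (total
# mental-health crises per year). Tier 2 matches the key outcomes of a
# crisis (hospitalizations, arrests, homelessness entries, suicides).
# Tier 3 matches the lower-level drivers (medication adherence, living
# arrangements).
tiers:
  - tier: 1
    metrics:
      - {metric: annual_crises, reference: 1000, tolerance: 0.20}
    tunable:
      - {path: "scale:patients.crisis_onset_weekly", lower: 0.25, upper: 4.0}
  - tier: 2
    metrics:
      - {metric: annual_hospitalizations, reference: 300, tolerance: 0.25}
      - {metric: annual_arrests, reference: 320, tolerance: 0.25}
      - {metric: annual_homelessness_entries, reference: 370, tolerance: 0.30}
      - {metric: annual_suicides, reference: 4, tolerance: 0.50}
    tunable:
      - {path: "scale:patients.propensity_to_commit_crime", lower: 0.25, upper: 4.0}
      - {path: "providers.hospital.capacity_per_week", lower: 1.0, upper: 6.0}
  - tier: 3
    metrics:
      - {metric: adherence_rate, reference: 0.55, tolerance: 0.20}
      - {metric: private_residence_share, reference: 0.64, tolerance: 0.20}
    tunable:
      - {path: "adherence_chart.start_threshold", lower: -0.5, upper: 0.6}
      - {path: "dynamics.untreated_decline", lower: 0.5, upper: 4.0}
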