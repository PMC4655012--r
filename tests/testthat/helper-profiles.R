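# Test profiles are built in code from the shipped default profile.

# default profile with a smaller population / shorter horizon
mini_profile <- function(n = 200, weeks = 52, reps = 4) {
  cfg <- load_default_profile()
  cfg <- config_set(cfg, "patients.population_size", as.integer(n))
  cfg <- config_set(cfg, "system.run_length_weeks", as.integer(weeks))
  config_set(cfg, "system.n_replications", as.integer(reps))
}

set_all <- function(cfg, path, value) {
  node <- config_get(cfg, path)
  config_set(cfg, path, rapply(list(node), function(x) value,
                               classes = "numeric", how = "replace")[[1]])
}

# profile with every stochastic rate and every score delta set to zero:
# the population state is a fixed point of the weekly update
frozen_profile <- function(n = 100, weeks = 26) {
  cfg <- mini_profile(n, weeks)
  for (p in c("patients.substance_start_weekly", "patients.substance_stop_weekly",
              "patients.employment_gain_weekly", "patients.employment_loss_weekly",
              "patients.plan_transfer_weekly", "patients.income_employed_weekly",
              "patients.benefits_weekly")) {
    cfg <- config_set(cfg, p, 0)
  }
  cfg <- set_all(cfg, "patients.crisis_onset_weekly", 0)
  cfg <- set_all(cfg, "patients.propensity_to_commit_crime", 0)
  for (p in c("medication_mh_effect", "untreated_decline", "crisis_mh_shock",
              "stress_mh_coef", "support_mh_coef", "mh_ph_coupling",
              "ph_mh_coupling", "side_effect_ph_coef",
              "financial_strain_stress", "stress_noise_sd")) {
    cfg <- config_set(cfg, paste0("dynamics.", p), 0)
  }
  for (e in c("private_residence", "assisted_living", "homeless",
              "hospital_inpatient", "correctional_facility")) {
    for (f in c("weekly_mh_effect", "weekly_ph_effect", "stress_level",
                "weekly_cost_patient")) {
      cfg <- config_set(cfg, paste0("environments.", e, ".", f), 0)
    }
  }
  for (p in c("cmhc", "case_worker", "csu", "hospital")) {
    cfg <- config_set(cfg, paste0("providers.", p, ".mh_effect_per_visit"), 0)
    cfg <- config_set(cfg, paste0("providers.", p, ".lai_probability"), 0)
  }
  # identity environment transitions
  for (e in c("private_residence", "assisted_living", "homeless")) {
    for (cc in c("severe", "serious", "moderate", "mild")) {
      row <- setNames(as.list(as.numeric(
        c("private_residence", "assisted_living", "homeless") == e)),
        c("private_residence", "assisted_living", "homeless"))
      cfg <- config_set(cfg, paste0("transitions.", e, ".", cc), row)
    }
  }
  # uniform weekly schedules so scheduled/missed counts are constant too
  cfg <- config_set(cfg, "patients.plan.cmhc_every", 1)
  cfg <- config_set(cfg, "patients.plan.caseworker_every", 1)
  # no medication, no attended appointments: no adherence or refill dynamics
  cfg <- config_set(cfg, "patients.plan.p_no_medicine", 1)
  cfg <- config_set(cfg, "patients.initial_on_medication", 0)
  cfg <- config_set(cfg, "levers.patient_appointment_compliance_rate", 0)
  cfg <- config_set(cfg, "patients.ph_decline_factor",
                    list(dist = "point", value = 0))
  cfg
}

# frozen profile plus a single crisis rate with inert outcomes: crisis
# arrivals are a pure counting process with weekly probability p
crisis_counting_profile <- function(p, n = 200, weeks = 52) {
  cfg <- frozen_profile(n, weeks)
  cfg <- set_all(cfg, "patients.crisis_onset_weekly", p)
  cfg <- config_set(cfg, "patients.crisis_outcomes",
                    list(hospitalization = 0, arrest = 0, homelessness = 0,
                         suicide = 0, stabilized = 1))
  # a stabilization with no unit capacity leaves the patient untouched
  cfg <- config_set(cfg, "providers.csu.capacity_per_week", 0)
  cfg
}

# a patient record (list) drawn from a profile
one_patient <- function(cfg, seed = 1, ...) {
  pop <- synthesize_population(cfg, seed = seed)
  p <- as.list(pop[1, ])
  p$environment <- as.character(p$environment)
  p$criminal_history <- as.character(p$criminal_history)
  mods <- list(...)
  for (nm in names(mods)) p[[nm]] <- mods[[nm]]
  p
}
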