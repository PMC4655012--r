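test_that("appointment attendance follows compliance, access and capacity", {
  cfg <- load_default_profile()
  pop <- synthesize_population(cfg, seed = 4)
  st <- new_ecosystem_state(cfg, pop)
  p <- as.list(pop[1, ]); p$environment <- "private_residence"

  zero <- config_set(cfg, "levers.patient_appointment_compliance_rate", 0)
  set.seed(1)
  expect_false(attempt_appointment(p, "case_worker", zero, st)$attended)

  sure <- config_set(cfg, "levers.patient_appointment_compliance_rate", 1)
  set.seed(1)
  out <- attempt_appointment(p, "case_worker", sure, st)  # cost factor 0
  expect_true(out$attended)
  expect_equal(out$third_party_cost,
               config_get(cfg, "providers.case_worker.third_party_cost"))

  expect_error(attempt_appointment(p, "acupuncturist", cfg, st),
               "unknown provider type")
})

test_that("a provider with weekly capacity 5 serves exactly 5 of 20 certain attendees", {
  cfg <- load_default_profile()
  cfg <- config_set(cfg, "levers.patient_appointment_compliance_rate", 1)
  cfg <- config_set(cfg, "providers.case_worker.count", 1L)
  cfg <- config_set(cfg, "providers.case_worker.capacity_per_week", 5)
  pop <- synthesize_population(config_set(cfg, "patients.population_size", 20L),
                               seed = 9)
  st <- new_ecosystem_state(cfg, pop)
  set.seed(2)
  attended <- 0L; blocked <- 0L
  for (i in seq_len(20)) {
    p <- as.list(pop[i, ]); p$environment <- "private_residence"
    out <- attempt_appointment(p, "case_worker", cfg, st)
    attended <- attended + out$attended
    blocked <- blocked + out$capacity_blocked
  }
  expect_identical(attended, 5L)
  expect_identical(blocked, 15L)
})

test_that("referral handoffs succeed per the lever and located probability", {
  cfg <- load_default_profile()
  p <- one_patient(cfg, environment = "private_residence")

  cfg1 <- config_set(cfg, "levers.handoff_success_rate", 1)
  cfg1 <- config_set(cfg1, "environments.private_residence.probability_of_being_located", 1)
  set.seed(1)
  ref <- refer_patient(p, cfg1)
  expect_true(ref$success)
  expect_false(ref$patient$lost_to_system)

  cfg0 <- config_set(cfg, "levers.handoff_success_rate", 0)
  ref <- refer_patient(p, cfg0)
  expect_false(ref$success)
  expect_true(ref$patient$lost_to_system)

  # binomial oracle at rate p with located probability 1
  rate <- 0.37
  cfgp <- config_set(cfg1, "levers.handoff_success_rate", rate)
  set.seed(31)
  hits <- sum(vapply(1:10000, function(i) refer_patient(p, cfgp)$success, NA))
  se <- sqrt(rate * (1 - rate) / 10000)
  expect_lt(abs(hits / 10000 - rate), 3 * se)
})

test_that("crisis resolution honours point-mass outcomes", {
  cfg <- load_default_profile()
  pop <- synthesize_population(cfg, seed = 6)
  st <- new_ecosystem_state(cfg, pop)
  p <- as.list(pop[1, ]); p$environment <- "private_residence"

  point <- function(outcome) {
    probs <- setNames(as.list(as.numeric(
      c("hospitalization", "arrest", "homelessness", "suicide",
        "stabilized") == outcome)),
      c("hospitalization", "arrest", "homelessness", "suicide", "stabilized"))
    config_set(cfg, "patients.crisis_outcomes", probs)
  }

  set.seed(1)
  res <- resolve_crisis(p, point("stabilized"), st)
  expect_equal(res$outcome, "stabilized")
  expect_equal(as.character(res$patient$environment), "private_residence")
  expect_true(res$provider_contact)

  res <- resolve_crisis(p, point("suicide"), st)
  expect_equal(res$outcome, "suicide")
  expect_false(res$patient$alive)

  res <- resolve_crisis(p, point("hospitalization"), st)
  expect_equal(res$outcome, "hospitalization")
  expect_equal(as.character(res$patient$environment), "hospital_inpatient")
  expect_gte(res$patient$environment_weeks_remaining, 1)

  res <- resolve_crisis(p, point("homelessness"), st)
  expect_equal(as.character(res$patient$environment), "homeless")
})

test_that("crisis outcome mix matches the configured distribution (multinomial, n = 10,000)", {
  cfg <- load_default_profile()
  probs <- unlist(cfg$patients$crisis_outcomes)
  pop <- synthesize_population(cfg, seed = 6)
  p <- as.list(pop[1, ]); p$environment <- "private_residence"
  set.seed(77)
  outs <- character(10000)
  for (i in 1:10000) {
    st <- new_ecosystem_state(cfg, NULL)  # fresh capacity every draw
    outs[i] <- resolve_crisis(p, cfg, st)$outcome
  }
  freq <- table(factor(outs, levels = names(probs))) / 10000
  for (nm in names(probs)) {
    se <- sqrt(probs[nm] * (1 - probs[nm]) / 10000)
    expect_lt(abs(freq[[nm]] - probs[[nm]]), 3 * se + 1e-12)
  }
})

test_that("arrests branch through CIT, diversion and incarceration as configured", {
  cfg <- load_default_profile()
  pop <- synthesize_population(cfg, seed = 6)
  p <- as.list(pop[1, ]); p$environment <- "private_residence"
  p$criminal_history <- "none"

  cit <- config_set(cfg, "justice.cit_officer_probability", 1)
  set.seed(1)
  st <- new_ecosystem_state(cfg, NULL)
  for (i in 1:20) {
    out <- process_arrest(p, cit, st)
    expect_equal(out$disposition, "cit_redirect")  # never incarcerated
  }

  det <- config_set(cfg, "justice.cit_officer_probability", 0)
  det <- config_set(det, "justice.jail_diversion_entry_probability", 0)
  det <- config_set(det, "justice.crime_degrees",
                    list(misdemeanor = 1, felony = 0))
  det <- config_set(det, "justice.sentence_weeks.misdemeanor",
                    list(mean = 12, min = 12))
  st <- new_ecosystem_state(det, NULL)
  out <- process_arrest(p, det, st)
  expect_equal(out$disposition, "incarcerated")
  expect_identical(out$sentence_weeks, 12)
  expect_equal(as.character(out$patient$environment), "correctional_facility")
  expect_equal(out$patient$criminal_history, "prior_misdemeanor")

  # probability tree oracle over 10,000 seeded arrests
  tree <- config_set(cfg, "justice.cit_officer_probability", 0.3)
  tree <- config_set(tree, "justice.crime_degrees",
                     list(misdemeanor = 0.6, felony = 0.4))
  tree <- config_set(tree, "justice.jail_diversion_entry_probability", 0.5)
  expected <- c(cit_redirect = 0.3, diversion = 0.7 * 0.6 * 0.5,
                incarcerated = 0.7 * (0.6 * 0.5 + 0.4))
  set.seed(13)
  disp <- character(10000)
  for (i in 1:10000) {
    st <- new_ecosystem_state(tree, NULL)
    disp[i] <- process_arrest(p, tree, st)$disposition
  }
  freq <- table(factor(disp, levels = names(expected))) / 10000
  for (nm in names(expected)) {
    se <- sqrt(expected[nm] * (1 - expected[nm]) / 10000)
    expect_lt(abs(freq[[nm]] - expected[[nm]]), 3 * se)
  }
})

test_that("jail release assigns discharge location and is subject to the handoff", {
  cfg <- load_default_profile()
  cfg <- config_set(cfg, "justice.discharge_location",
                    list(private_residence = 1, assisted_living = 0, homeless = 0))
  p <- one_patient(cfg, environment = "correctional_facility",
                   environment_weeks_remaining = 0L, medicine = NA_character_)

  sure <- config_set(cfg, "levers.handoff_success_rate", 1)
  sure <- config_set(sure, "environments.private_residence.probability_of_being_located", 1)
  set.seed(2)
  rel <- release_from_jail(p, sure)
  expect_equal(as.character(rel$environment), "private_residence")
  expect_true(rel$released_ever)
  expect_false(rel$lost_to_system)
  expect_false(is.na(rel$medicine))  # discharge plan includes a prescription

  none <- config_set(cfg, "levers.handoff_success_rate", 0)
  rel <- release_from_jail(p, none)
  expect_true(rel$lost_to_system)
})

test_that("a re-arrest after release counts exactly one recidivist", {
  # scripted engine fixture: one patient, certain weekly crime, short
  # deterministic sentences, no other dynamics
  cfg <- frozen_profile(n = 1, weeks = 20)
  cfg <- set_all(cfg, "patients.propensity_to_commit_crime", 1)
  cfg <- config_set(cfg, "justice.cit_officer_probability", 0)
  cfg <- config_set(cfg, "justice.jail_diversion_entry_probability", 0)
  cfg <- config_set(cfg, "justice.crime_degrees", list(misdemeanor = 1, felony = 0))
  cfg <- config_set(cfg, "justice.sentence_weeks.misdemeanor", list(mean = 2, min = 2))
  r <- run_simulation(cfg, seed = 5)
  expect_gte(sum(r$metrics$releases), 2)
  expect_gte(r$n_released, 1)
  expect_identical(r$n_rearrested, 1L)       # distinct recidivists, not events
  expect_equal(r$summary$recidivism_rate, 1)
})
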