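test_that("adherence chart transitions follow the factor score with hysteresis", {
  cfg <- load_default_profile()
  chart <- cfg$adherence_chart

  # neutral factors, thresholds straddling 0: no transition either way
  p <- one_patient(cfg, on_medication = TRUE, medicine = "oral_sga",
                   lai_weeks_left = 0, family_support = 0, substance_abuse = FALSE)
  neutral <- list(stress = 0, recent_provider_contact = FALSE,
                  side_effect_severity = 0, cost_to_patient_factor = 0)
  expect_true(adherence_step(p, chart, neutral)$on_medication)
  p$on_medication <- FALSE
  expect_false(adherence_step(p, chart, neutral)$on_medication)

  # maximal stress and substance abuse, no support: transitions off under
  # the shipped weights
  p_off <- one_patient(cfg, on_medication = TRUE, medicine = "oral_sga",
                       lai_weeks_left = 0, substance_abuse = TRUE,
                       family_support = 0)
  ctx <- list(stress = 1, recent_provider_contact = FALSE,
              side_effect_severity = 2, cost_to_patient_factor = 2)
  stepped <- adherence_step(p_off, chart, ctx)
  expect_lt(stepped$adherence_score, chart$stop_threshold)
  expect_false(stepped$on_medication)

  # an active long-acting injectable suppresses the off-transition
  p_lai <- p_off
  p_lai$medicine <- "lai_sga"
  p_lai$lai_weeks_left <- 6
  expect_true(adherence_step(p_lai, chart, ctx)$on_medication)

  # a score exactly at the start threshold stays off (strict inequality)
  w <- chart$factor_weights
  chart_eq <- chart
  chart_eq$start_threshold <- w$recent_provider_contact  # score == threshold
  ctx_eq <- list(stress = 0, recent_provider_contact = TRUE,
                 side_effect_severity = 0, cost_to_patient_factor = 0)
  p_eq <- one_patient(cfg, on_medication = FALSE, medicine = "oral_sga",
                      lai_weeks_left = 0, substance_abuse = FALSE,
                      family_support = 0)
  stepped <- adherence_step(p_eq, chart_eq, ctx_eq)
  expect_identical(stepped$adherence_score, chart_eq$start_threshold)
  expect_false(stepped$on_medication)

  # a patient with no medicine in plan is a no-op
  p_none <- one_patient(cfg, medicine = NA_character_, on_medication = FALSE)
  expect_identical(adherence_step(p_none, chart, neutral)$on_medication, FALSE)
})

test_that("mental-health update clamps at the floor and declines while untreated", {
  cfg <- frozen_profile()
  p <- one_patient(cfg, mental_health = 50, mh_floor = 20,
                   physical_health = 50, family_support = 0.5)

  # all deltas zero: identity
  expect_equal(update_mental_health(p, cfg, list()), 50)

  # a huge negative shock stops exactly at the floor
  expect_equal(update_mental_health(p, cfg, list(crisis_shock = -500)), 20)
  expect_equal(update_mental_health(p, cfg, list(crisis_shock = 500)), 100)

  # untreated decline: k-step iteration matches the closed form until the floor
  cfg2 <- config_set(cfg, "dynamics.untreated_decline", 1.5)
  p$on_medication <- FALSE
  traj <- numeric(30)
  s <- p$mental_health
  for (k in 1:30) {
    q <- p; q$mental_health <- s
    s <- update_mental_health(q, cfg2, list(provider_contact = FALSE))
    traj[k] <- s
  }
  expect_equal(traj, pmax(20, 50 - 1.5 * (1:30)))
  expect_true(all(diff(traj) <= 0))

  # provider contact suspends the untreated decline
  expect_equal(update_mental_health(p, cfg2, list(provider_contact = TRUE)), 50)
})

test_that("physical-health update carries side-effect burden and mental coupling", {
  cfg <- frozen_profile()
  p <- one_patient(cfg, physical_health = 60, mental_health = 60,
                   ph_decline_factor = 0, medicine = "oral_sga",
                   on_medication = TRUE)
  expect_equal(update_physical_health(p, frozen_profile(), list()), 60)

  cfg_se <- config_set(cfg, "dynamics.side_effect_ph_coef", 0.1)
  expect_lt(update_physical_health(p, cfg_se, list()), 60)
  p_off <- p; p_off$on_medication <- FALSE
  expect_equal(update_physical_health(p_off, cfg_se, list()), 60)

  cfg_cp <- config_set(cfg, "dynamics.ph_mh_coupling", 0.5)
  hi <- p; hi$mental_health <- 80
  lo <- p; lo$mental_health <- 20
  expect_gte(update_physical_health(hi, cfg_cp, list()),
             update_physical_health(lo, cfg_cp, list()))
})

test_that("critical outcomes respect priority and configured rates", {
  cfg <- frozen_profile()
  p <- one_patient(cfg, mental_health = 50, employed = FALSE,
                   substance_abuse = FALSE)
  set.seed(1)
  expect_equal(draw_critical_outcomes(p, cfg)$kind, "none")

  cfg_crisis <- set_all(cfg, "patients.crisis_onset_weekly", 1)
  expect_equal(draw_critical_outcomes(p, cfg_crisis)$kind, "crisis")

  # binomial oracle: empirical crisis frequency within 3 SE of p
  p_rate <- 0.07
  cfg_p <- set_all(cfg, "patients.crisis_onset_weekly", p_rate)
  set.seed(99)
  hits <- sum(vapply(1:10000, function(i)
    draw_critical_outcomes(p, cfg_p)$kind == "crisis", NA))
  se <- sqrt(p_rate * (1 - p_rate) / 10000)
  expect_lt(abs(hits / 10000 - p_rate), 3 * se)
})

test_that("environment transitions follow the category row, capacity and overflow", {
  cfg <- load_default_profile()
  p <- one_patient(cfg, environment = "private_residence", mental_health = 90,
                   environment_weeks_remaining = NA_integer_)

  # absorbing row: no move
  cfg_abs <- config_set(cfg, "transitions.private_residence.mild",
                        list(private_residence = 1, assisted_living = 0,
                             homeless = 0))
  expect_equal(transition_environment(p, cfg_abs), "private_residence")

  # full destination overflows to homeless
  cfg_full <- config_set(cfg, "transitions.private_residence.mild",
                         list(private_residence = 0, assisted_living = 1,
                              homeless = 0))
  occ <- setNames(c(0L, 140L, 0L, 0L, 0L),
                  c("private_residence", "assisted_living", "homeless",
                    "hospital_inpatient", "correctional_facility"))
  set.seed(5)
  expect_equal(transition_environment(p, cfg_full, occ), "homeless")

  # episodic environments are rejected, mid-stay patients do not move
  p_hosp <- p; p_hosp$environment <- "hospital_inpatient"
  expect_error(transition_environment(p_hosp, cfg), "episodic")
  p_stay <- p; p_stay$environment_weeks_remaining <- 3L
  expect_equal(transition_environment(p_stay, cfg), "private_residence")

  # multinomial oracle on a fixed row at n = 10,000
  row <- c(private_residence = 0.6, assisted_living = 0.3, homeless = 0.1)
  cfg_row <- config_set(cfg, "transitions.private_residence.mild",
                        as.list(row))
  set.seed(123)
  draws <- vapply(1:10000, function(i) transition_environment(p, cfg_row), "")
  freq <- table(factor(draws, levels = names(row))) / 10000
  for (nm in names(row)) {
    se <- sqrt(row[nm] * (1 - row[nm]) / 10000)
    expect_lt(abs(freq[[nm]] - row[[nm]]), 3 * se)
  }
})

test_that("weekly_update is a fixed point under frozen dynamics and reproducible", {
  cfg <- frozen_profile()
  pop <- synthesize_population(cfg, seed = 8)
  st <- new_ecosystem_state(cfg, pop)
  p <- as.list(pop[1, ])
  p$environment <- as.character(p$environment)

  out <- weekly_update(p, cfg, st, week = 1)
  for (f in c("mental_health", "physical_health", "environment",
              "on_medication", "financial_resources", "lost_to_system",
              "employed", "substance_abuse")) {
    expect_equal(out$patient[[f]], p[[f]], info = f)
  }

  set.seed(21); a <- weekly_update(p, load_default_profile(), st, week = 1)
  set.seed(21); b <- weekly_update(p, load_default_profile(), st, week = 1)
  expect_equal(a$patient, b$patient)
  expect_equal(a$events, b$events)
})

test_that("weekly_update emits exactly one crisis under a certain crisis rate", {
  cfg <- crisis_counting_profile(1, n = 20, weeks = 4)
  pop <- synthesize_population(cfg, seed = 2)
  st <- new_ecosystem_state(cfg, pop)
  p <- as.list(pop[1, ]); p$environment <- as.character(p$environment)
  set.seed(3)
  out <- weekly_update(p, cfg, st, week = 1)
  expect_equal(sum(out$events$kind == "crisis"), 1)
  expect_equal(sum(out$events$kind == "crisis_stabilized"), 1)
})
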