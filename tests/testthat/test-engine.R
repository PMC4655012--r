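test_that("runs are bit-reproducible given (config, seed)", {
  cfg <- mini_profile(n = 150, weeks = 30)
  a <- run_simulation(cfg, seed = 17)
  b <- run_simulation(cfg, seed = 17)
  expect_identical(a$metrics, b$metrics)
  expect_identical(a$costs, b$costs)
  expect_identical(a$final_state, b$final_state)
  expect_identical(a$config_hash, b$config_hash)
  c2 <- run_simulation(cfg, seed = 18)
  expect_false(identical(a$metrics, c2$metrics))
})

test_that("a zero-length run yields an empty series and an initial summary", {
  cfg <- mini_profile(n = 50)
  r <- run_simulation(cfg, seed = 1, n_weeks = 0)
  expect_identical(nrow(r$metrics), 0L)
  expect_identical(r$summary$n_weeks, 0L)
  expect_identical(r$population_size, 50L)
})

test_that("frozen dynamics are a fixed point of the weekly update over 260 weeks", {
  cfg <- frozen_profile(n = 120, weeks = 260)
  r <- run_simulation(cfg, seed = 23)
  m <- r$metrics[, setdiff(names(r$metrics), "week")]
  for (col in names(m)) {
    expect_true(all(m[[col]] == m[[col]][1]), info = col)
  }
  expect_equal(r$summary$annual_crises, 0)
})

test_that("population, category and environment counts are conserved every week", {
  cfg <- mini_profile(n = 300, weeks = 60)
  r <- run_simulation(cfg, seed = 31)
  m <- r$metrics
  expect_true(all(m$alive + cumsum(m$suicides) == 300))
  expect_true(all(m$cat_severe + m$cat_serious + m$cat_moderate +
                    m$cat_mild == m$alive))
  expect_true(all(m$env_private_residence + m$env_assisted_living +
                    m$env_homeless + m$env_hospital_inpatient +
                    m$env_correctional_facility == m$alive))
  expect_true(all(m$appts_kept + m$appts_missed == m$appts_scheduled))
})

test_that("weekly attendances never exceed provider capacity", {
  cfg <- mini_profile(n = 400, weeks = 60)
  r <- run_simulation(cfg, seed = 37)
  m <- r$metrics
  cap <- function(id) config_get(cfg, paste0("providers.", id, ".count")) *
    config_get(cfg, paste0("providers.", id, ".capacity_per_week"))
  expect_true(all(m$cmhc_visits <= cap("cmhc")))
  expect_true(all(m$caseworker_visits <= cap("case_worker")))
  expect_true(all(m$csu_contacts <= cap("csu")))
  expect_true(all(m$hospital_admissions <= cap("hospital")))
  expect_true(all(m$env_hospital_inpatient <=
                    config_get(cfg, "environments.hospital_inpatient.capacity")))
})

test_that("scores stay inside [1,100] and above each patient's floor", {
  cfg <- mini_profile(n = 300, weeks = 104)
  r <- run_simulation(cfg, seed = 41)
  f <- r$final_state
  pop <- r$initial_population
  alive <- f$alive
  expect_true(all(f$mental_health[alive] >= pop$mh_floor[alive]))
  expect_true(all(f$mental_health[alive] <= 100))
  expect_true(all(f$physical_health[alive] >= 1))
  expect_true(all(f$physical_health[alive] <= 100))
})

test_that("the cost ledger agrees with the event log posting for posting", {
  cfg <- mini_profile(n = 100, weeks = 30)
  r <- run_simulation(cfg, seed = 43, log_events = TRUE)
  ev <- r$events
  cost_ev <- ev[startsWith(ev$kind, "cost_"), ]
  # every costed event appears once in the log; weekly ledger sums match
  for (cat in c("medication", "outpatient", "hospitalization",
                "incarceration", "housing", "crisis_services")) {
    from_log <- sum(cost_ev$value[cost_ev$kind == paste0("cost_", cat)])
    from_ledger <- sum(r$costs[[paste0(cat, "_patient")]] +
                         r$costs[[paste0(cat, "_third_party")]])
    expect_equal(from_log, from_ledger, info = cat)
  }
})

test_that("adherence tracking equals on-medication counts recomputed from the event log", {
  cfg <- mini_profile(n = 150, weeks = 40)
  r <- run_simulation(cfg, seed = 47, log_events = TRUE)
  ev <- r$events
  starts <- tabulate(ev$week[ev$kind == "med_start"], nbins = 40)
  stops <- tabulate(ev$week[ev$kind == "med_stop"], nbins = 40)
  recon <- sum(r$initial_population$on_medication) + cumsum(starts - stops)
  expect_equal(r$metrics$on_medication, recon)
})

test_that("replication pooling reports means and standard errors", {
  cfg <- frozen_profile(n = 80, weeks = 20)
  one <- run_replications(cfg, n = 1, base_seed = 5)
  expect_true(all(is.na(one$pooled$se)))
  expect_equal(one$pooled$n[1], 1)

  frozen <- run_replications(cfg, n = 5, base_seed = 5)
  expect_true(all(frozen$pooled$sd[frozen$pooled$metric == "annual_crises"] == 0))

  # binomial oracle: crisis probability p on otherwise frozen dynamics
  p <- 0.02
  cfgp <- crisis_counting_profile(p, n = 200, weeks = 52)
  rr <- run_replications(cfgp, n = 10, base_seed = 11)
  mu <- rr$pooled$mean[rr$pooled$metric == "annual_crises"]
  se <- rr$pooled$se[rr$pooled$metric == "annual_crises"]
  expect_lt(abs(mu - 200 * 52 * p), 3 * max(se, 1e-9))
})

test_that("exports round-trip and the manifest identifies the run", {
  cfg <- mini_profile(n = 60, weeks = 20)
  r <- run_simulation(cfg, seed = 53, log_events = TRUE)
  out <- file.path(tempdir(), "spmi-export-test")
  paths <- export_results(r, out)
  metrics <- read.csv(paths[["metrics"]])
  expect_equal(metrics$on_medication, r$metrics$on_medication)
  costs <- read.csv(paths[["costs"]])
  expect_equal(costs$incarceration_third_party,
               r$costs$incarceration_third_party)
  man <- jsonlite::read_json(paths[["manifest"]])
  expect_equal(man$config_hash, config_hash(cfg))
  expect_equal(man$seed, 53L)
  expect_true(file.exists(paths[["events"]]))
  unlink(out, recursive = TRUE)
})

test_that("engine and single-patient reference produce identical deterministic trajectories", {
  # frozen stochastics, but non-trivial deterministic drift: untreated
  # decline plus environment effects
  cfg <- frozen_profile(n = 40, weeks = 8)
  cfg <- config_set(cfg, "dynamics.untreated_decline", 1.7)
  cfg <- config_set(cfg, "dynamics.support_mh_coef", 0.4)
  cfg <- config_set(cfg, "environments.private_residence.weekly_mh_effect", 0.3)
  cfg <- config_set(cfg, "environments.homeless.weekly_mh_effect", -0.9)
  cfg <- config_set(cfg, "environments.homeless.weekly_ph_effect", -0.5)

  r <- run_simulation(cfg, seed = 61)
  set.seed(61)
  pop <- synthesize_population(cfg)
  st <- new_ecosystem_state(cfg, pop)
  mh <- numeric(nrow(pop))
  ph <- numeric(nrow(pop))
  for (i in seq_len(nrow(pop))) {
    p <- as.list(pop[i, ])
    p$environment <- as.character(p$environment)
    for (w in 1:8) {
      p <- weekly_update(p, cfg, st, week = w)$patient
    }
    mh[i] <- p$mental_health
    ph[i] <- p$physical_health
  }
  expect_equal(r$final_state$mental_health, mh)
  expect_equal(r$final_state$physical_health, ph)
})

test_that("being on medication never lowers the expected mental-health trajectory", {
  cfg <- frozen_profile()
  cfg <- config_set(cfg, "dynamics.untreated_decline", 1.5)
  cfg <- config_set(cfg, "dynamics.medication_mh_effect", 0.8)
  p_on <- one_patient(cfg, mental_health = 70, mh_floor = 10,
                      on_medication = TRUE, medicine = "oral_sga")
  p_off <- p_on; p_off$on_medication <- FALSE
  for (k in 1:20) {
    p_on$mental_health <- update_mental_health(p_on, cfg, list())
    p_off$mental_health <- update_mental_health(p_off, cfg, list())
    expect_gte(p_on$mental_health, p_off$mental_health)
  }
})
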