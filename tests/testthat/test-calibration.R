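test_that("shipped targets file parses and its tiers are well-formed", {
  tg <- load_calibration_targets()
  expect_s3_class(tg, "spmi_calibration_targets")
  tiers <- vapply(tg$tiers, function(t) t$tier, 0)
  expect_equal(tiers, sort(tiers))
  expect_equal(tg$tiers[[1]]$metrics[[1]]$metric, "annual_crises")
  expect_true(all(vapply(tg$tiers, function(t)
    all(vapply(t$metrics, function(m) m$tolerance > 0, NA)), NA)))
})

test_that("targets already satisfied leave the profile untouched and converge", {
  p <- 0.02
  cfg <- crisis_counting_profile(p, n = 200, weeks = 52)
  ref <- 200 * 52 * p
  targets <- structure(list(tiers = list(list(
    tier = 1,
    metrics = list(list(metric = "annual_crises", reference = ref,
                        tolerance = 0.20)),
    tunable = list(list(path = "scale:patients.crisis_onset_weekly",
                        lower = 0.25, upper = 4))))),
    class = "spmi_calibration_targets")
  res <- calibrate(cfg, targets, n_reps = 3, budget = 20, base_seed = 9)
  expect_true(res$converged)
  expect_equal(unclass(res$config), unclass(cfg))   # no search was needed
  expect_true(all(res$achieved$within_tolerance))
})

test_that("calibration inverts a single binomial rate to within 5%", {
  # analytic oracle: annual crises = N x 52 x p, so a reference of
  # N x 52 x p* is recovered by scaling the starting rate p0 toward p*
  p_star <- 0.03
  p0 <- 0.012
  n <- 300
  cfg <- crisis_counting_profile(p0, n = n, weeks = 52)
  targets <- structure(list(tiers = list(list(
    tier = 1,
    metrics = list(list(metric = "annual_crises",
                        reference = n * 52 * p_star, tolerance = 0.02)),
    tunable = list(list(path = "scale:patients.crisis_onset_weekly",
                        lower = 0.25, upper = 6))))),
    class = "spmi_calibration_targets")
  res <- calibrate(cfg, targets, n_reps = 4, budget = 40, base_seed = 10)
  recovered <- res$config$patients$crisis_onset_weekly$severe
  expect_lt(abs(recovered - p_star) / p_star, 0.05)
  expect_true(res$converged)
})

test_that("calibration never returns an invalid profile and reports every target", {
  tg <- load_calibration_targets()
  cfg <- mini_profile(n = 250, weeks = 52, reps = 2)
  res <- calibrate(cfg, tg, n_reps = 2, budget = 12, base_seed = 3)
  expect_identical(nrow(validate_config(res$config)), 0L)
  n_targets <- sum(vapply(tg$tiers, function(t) length(t$metrics), 0L))
  expect_identical(nrow(res$achieved), as.integer(n_targets))
  expect_true(all(c("rel_error", "within_tolerance") %in% names(res$achieved)))
})

test_that("variability is zero under frozen dynamics and flags only the perturbed class", {
  r <- run_simulation(frozen_profile(n = 150, weeks = 52), seed = 19)
  v <- variability_check(r, bounds = 0.5)
  expect_true(all(v$variability[!is.na(v$variability)] == 0))
  expect_false(any(v$flagged))

  # perturb only the severe class: crises fire only at severe scores and
  # the stabilization contact moves the score
  cfg <- frozen_profile(n = 400, weeks = 52)
  cfg <- config_set(cfg, "patients.crisis_onset_weekly",
                    list(severe = 0.3, serious = 0, moderate = 0, mild = 0))
  cfg <- config_set(cfg, "patients.crisis_outcomes",
                    list(hospitalization = 0, arrest = 0, homelessness = 0,
                         suicide = 0, stabilized = 1))
  cfg <- config_set(cfg, "providers.csu.mh_effect_per_visit", 4)
  r2 <- run_simulation(cfg, seed = 20)
  v2 <- variability_check(r2, bounds = 0.5)
  expect_true(v2$flagged[v2$class == "severe"])
  expect_false(any(v2$flagged[v2$class != "severe"]))
})

test_that("temporal variability of a clamped random-walk score matches a direct Monte-Carlo oracle", {
  # profile whose mental-health update reduces to a zero-drift random walk:
  # step = support x family - stress x clamp01(base + noise) = -noise
  walk_profile <- function(n) {
    cfg <- frozen_profile(n = n, weeks = 260)
    cfg <- config_set(cfg, "patients.initial_mental_health",
                      list(dist = "point", value = 55))
    cfg <- config_set(cfg, "patients.mh_floor", list(dist = "point", value = 1))
    cfg <- config_set(cfg, "patients.stress_base", list(dist = "point", value = 0.5))
    cfg <- config_set(cfg, "patients.family_support", list(dist = "point", value = 0.5))
    cfg <- config_set(cfg, "dynamics.stress_mh_coef", 1)
    cfg <- config_set(cfg, "dynamics.support_mh_coef", 1)
    config_set(cfg, "dynamics.stress_noise_sd", 0.1)
  }
  n <- 50
  cfg <- walk_profile(n)
  reps <- 40
  stat <- vapply(seq_len(reps), function(i) {
    r <- run_simulation(cfg, seed = 100 + i)
    variability_check(r)$variability[3]  # all patients are class "moderate"
  }, 0)

  set.seed(1234)
  oracle <- vapply(seq_len(400), function(i) {
    steps <- matrix(rnorm(260 * n, 0, 0.1), nrow = 260)
    sd(pmin(100, pmax(1, 55 - cumsum(rowMeans(steps)))))
  }, 0)
  expect_lt(abs(mean(stat) - mean(oracle)) / mean(oracle), 0.10)
})
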