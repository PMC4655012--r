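.metric_names <- c(
  "alive", "cat_severe", "cat_serious", "cat_moderate", "cat_mild",
  "env_private_residence", "env_assisted_living", "env_homeless",
  "env_hospital_inpatient", "env_correctional_facility",
  "on_medication", "lost_to_system", "crises", "hospital_admissions",
  "arrests", "incarcerations", "suicides", "homeless_entries",
  "stabilizations", "cit_redirects", "diversions", "releases", "rearrests",
  "appts_scheduled", "appts_kept", "appts_missed", "referrals_attempted",
  "referrals_failed", "crimes", "cmhc_visits", "caseworker_visits",
  "csu_contacts", "in_diversion", "employed", "substance_abuse",
  "mean_mental_health", "mean_physical_health", "med_starts", "med_stops",
  "class_mh_severe", "class_mh_serious", "class_mh_moderate", "class_mh_mild")

#' Event kinds emitted by the simulation engine
#'
#' Integer codes used in the engine's event log; `engine_event_kinds()`
#' returns the code-to-name mapping.
#'
#' @return Named integer vector.
#' @export
engine_event_kinds <- function() {
  c(crisis = 1L, crime = 2L, substance_start = 3L, substance_stop = 4L,
    employment_found = 5L, employment_lost = 6L, crisis_hospitalization = 7L,
    crisis_arrest = 8L, crisis_homelessness = 9L, crisis_suicide = 10L,
    crisis_stabilized = 11L, csu_contact = 12L, cit_redirect = 13L,
    diversion_entry = 14L, incarcerate = 15L, release = 16L,
    homeless_entry = 17L, appt_kept = 18L, appt_missed = 19L,
    refill_fail = 20L, med_start = 21L, med_stop = 22L, referral_ok = 23L,
    referral_fail = 24L, outreach_reengaged = 25L, env_move = 26L,
    cost_medication = 30L, cost_outpatient = 31L, cost_hospitalization = 32L,
    cost_incarceration = 33L, cost_housing = 34L, cost_crisis_services = 35L)
}

.build_engine_pack <- function(cfg) {
  meds <- cfg$medicines
  med_ids <- vapply(meds, function(m) m$id, "")
  is_lai <- vapply(meds, function(m) isTRUE(m$is_long_acting_injectable), NA)
  provs <- lapply(setNames(.provider_types, .provider_types),
                  function(t) .provider_by_type(cfg, t))
  envs <- lapply(setNames(.envs_all, .envs_all),
                 function(id) .env_by_id(cfg, id))
  hosp_los <- envs$hospital_inpatient$length_of_stay_weeks
  tr <- numeric(3 * 4 * 3)
  for (e in seq_along(.envs_stable)) {
    for (cc in seq_along(.mh_categories)) {
      row <- unlist(cfg$transitions[[.envs_stable[e]]][[.mh_categories[cc]]])
      base <- ((e - 1) * 4 + (cc - 1)) * 3
      tr[base + seq_len(3)] <- as.numeric(row[.envs_stable])
    }
  }
  tr[is.na(tr)] <- 0
  pa <- cfg$patients
  dy <- cfg$dynamics
  ec <- cfg$economics
  ju <- cfg$justice
  list(
    handoff = cfg$levers$handoff_success_rate,
    compliance = cfg$levers$patient_appointment_compliance_rate,
    outreach = cfg$levers$outreach_probability %||% 0,
    adherence_weights = as.numeric(unlist(
      cfg$adherence_chart$factor_weights)[.adherence_factors]),
    stop_threshold = cfg$adherence_chart$stop_threshold,
    start_threshold = cfg$adherence_chart$start_threshold,
    medication_mh_effect = dy$medication_mh_effect,
    untreated_decline = dy$untreated_decline,
    crisis_mh_shock = dy$crisis_mh_shock,
    stress_mh_coef = dy$stress_mh_coef,
    support_mh_coef = dy$support_mh_coef,
    mh_ph_coupling = dy$mh_ph_coupling,
    ph_mh_coupling = dy$ph_mh_coupling,
    side_effect_ph_coef = dy$side_effect_ph_coef,
    financial_strain_stress = dy$financial_strain_stress,
    stress_noise_sd = dy$stress_noise_sd,
    resources_ref = ec$resources_ref,
    access_floor = ec$access_floor,
    copay_per_factor_medication = ec$copay_per_factor_medication,
    copay_per_factor_visit = ec$copay_per_factor_visit,
    low_resources_threshold = ec$low_resources_threshold,
    plan_transfer_weekly = pa$plan_transfer_weekly,
    substance_start_weekly = pa$substance_start_weekly,
    substance_stop_weekly = pa$substance_stop_weekly,
    employment_gain_weekly = pa$employment_gain_weekly,
    employment_loss_weekly = pa$employment_loss_weekly,
    employment_min_mh = pa$employment_min_mh,
    income_employed_weekly = pa$income_employed_weekly,
    benefits_weekly = pa$benefits_weekly,
    crisis_onset = as.numeric(unlist(pa$crisis_onset_weekly)[.mh_categories]),
    crime_propensity = as.numeric(unlist(
      pa$propensity_to_commit_crime)[.mh_categories]),
    crisis_outcomes = as.numeric(unlist(pa$crisis_outcomes)[.crisis_outcomes]),
    med_refill = vapply(meds, function(m) as.integer(m$refill_frequency_weeks), 0L),
    med_cost_factor = vapply(meds, function(m) as.integer(m$cost_to_patient_factor), 0L),
    med_system_cost = vapply(meds, function(m) as.numeric(m$system_cost_per_week), 0),
    med_side_effect_total = vapply(meds, function(m)
      m$short_term_side_effect_severity + m$long_term_side_effect_severity, 0),
    med_long_se = vapply(meds, function(m)
      as.numeric(m$long_term_side_effect_severity), 0),
    med_is_lai = is_lai,
    lai_idx = which(is_lai)[1] - 1L,
    oral_idx = which(!is_lai)[1] - 1L,
    provider_capacity = vapply(provs, function(p)
      as.numeric(p$count * p$capacity_per_week), 0),
    provider_lai_prob = vapply(provs, function(p) as.numeric(p$lai_probability), 0),
    provider_cost_factor = vapply(provs, function(p)
      as.integer(p$cost_to_patient_factor), 0L),
    provider_third_cost = vapply(provs, function(p)
      as.numeric(p$third_party_cost), 0),
    provider_mh_effect = vapply(provs, function(p)
      as.numeric(p$mh_effect_per_visit), 0),
    env_p_located = vapply(envs, function(e)
      as.numeric(e$probability_of_being_located), 0),
    env_capacity = vapply(envs, function(e) as.numeric(e$capacity), 0),
    env_mh_effect = vapply(envs, function(e) as.numeric(e$weekly_mh_effect), 0),
    env_ph_effect = vapply(envs, function(e) as.numeric(e$weekly_ph_effect), 0),
    env_cost_patient = vapply(envs, function(e)
      as.numeric(e$weekly_cost_patient), 0),
    env_cost_third = vapply(envs, function(e)
      as.numeric(e$weekly_cost_third_party), 0),
    env_stress = vapply(envs, function(e) as.numeric(e$stress_level), 0),
    hospital_los_mean = hosp_los$mean,
    hospital_los_min = hosp_los$min,
    transitions = tr,
    cit_probability = ju$cit_officer_probability,
    p_misdemeanor = ju$crime_degrees$misdemeanor,
    sentence_mean = c(ju$sentence_weeks$misdemeanor$mean,
                      ju$sentence_weeks$felony$mean),
    sentence_min = c(ju$sentence_weeks$misdemeanor$min,
                     ju$sentence_weeks$felony$min),
    diversion_probability = ju$jail_diversion_entry_probability,
    diversion_weeks = as.integer(ju$diversion_weeks),
    discharge_location = {
      d <- unlist(ju$discharge_location)
      out <- setNames(numeric(3), .envs_stable)
      out[names(d)] <- d
      as.numeric(out)
    },
    cmhc_every = as.integer(cfg$patients$plan$cmhc_every),
    cw_every = as.integer(cfg$patients$plan$caseworker_every)
  )
}

.pop_to_engine <- function(pop, cfg) {
  med_ids <- vapply(cfg$medicines, function(m) m$id, "")
  list(
    mental_health = pop$mental_health,
    mh_floor = pop$mh_floor,
    physical_health = pop$physical_health,
    ph_decline_factor = pop$ph_decline_factor,
    stress_base = pop$stress_base,
    family_support = pop$family_support,
    substance_abuse = pop$substance_abuse,
    employed = pop$employed,
    on_medication = pop$on_medication,
    medicine_idx = ifelse(is.na(pop$medicine), -1L,
                          match(pop$medicine, med_ids) - 1L),
    lai_weeks_left = as.numeric(pop$lai_weeks_left),
    environment_idx = as.integer(pop$environment) - 1L,
    weeks_remaining = ifelse(is.na(pop$environment_weeks_remaining), -1L,
                             as.integer(pop$environment_weeks_remaining)),
    financial_resources = pop$financial_resources,
    criminal_history_idx = as.integer(pop$criminal_history) - 1L,
    in_jail_diversion = pop$in_jail_diversion,
    lost_to_system = pop$lost_to_system,
    appointment_phase = as.integer(pop$appointment_phase),
    refill_phase = as.integer(pop$refill_phase)
  )
}

#' Run one full simulation
#'
#' Synthesizes the patient population from the profile, then iterates the
#' weekly decision sequence for `run_length_weeks` ticks with a shared
#' ecosystem state (provider capacities, environment occupancy) and a cost
#' ledger, aggregating weekly metrics at the end of every tick. The run is
#' bit-reproducible given `(cfg, seed)`.
#'
#' @param cfg A validated `spmi_config`.
#' @param seed Integer seed (default: the profile's `system.seed`).
#' @param log_events If `TRUE`, keep the full typed event log (one row per
#'   event); sized for diagnostic runs, not sweeps.
#' @param n_weeks Override of the profile's run length (used for short
#'   diagnostic runs).
#' @return An `spmi_run_result`: weekly `metrics` and `costs` data frames,
#'   an end-of-run `summary` list, the `final_state` of the population, the
#'   profile hash and seed, and (optionally) `events`.
#' @export
run_simulation <- function(cfg, seed = cfg$system$seed, log_events = FALSE,
                           n_weeks = cfg$system$run_length_weeks) {
  v <- validate_config(cfg)
  if (nrow(v) > 0L) {
    stop("invalid config: ", v$field[1], ": ", v$constraint[1], call. = FALSE)
  }
  n_weeks <- as.integer(n_weeks)
  set.seed(as.integer(seed))
  pop <- synthesize_population(cfg)

  if (n_weeks == 0L || nrow(pop) == 0L) {
    metrics <- as.data.frame(matrix(numeric(0), nrow = 0,
                                    ncol = length(.metric_names),
                                    dimnames = list(NULL, .metric_names)))
    costs <- as.data.frame(matrix(numeric(0), nrow = 0, ncol = 12))
    raw <- NULL
  } else {
    raw <- .cpp_run_engine(.build_engine_pack(cfg), .pop_to_engine(pop, cfg),
                           n_weeks, log_events)
    metrics <- as.data.frame(raw$metrics)
    names(metrics) <- .metric_names
    costs <- as.data.frame(raw$costs)
  }
  names(costs) <- paste0(rep(.cost_categories, each = 2L),
                         c("_patient", "_third_party"))
  metrics <- cbind(week = seq_len(nrow(metrics)), metrics)
  costs <- cbind(week = seq_len(nrow(costs)), costs)

  events <- NULL
  if (log_events && !is.null(raw) && !is.null(raw$events)) {
    kinds <- engine_event_kinds()
    events <- data.frame(
      week = raw$events$week, patient = raw$events$patient,
      kind = names(kinds)[match(raw$events$kind, kinds)],
      value = raw$events$value, stringsAsFactors = FALSE)
  }

  res <- structure(list(
    config_hash = config_hash(cfg), seed = as.integer(seed),
    n_weeks = n_weeks, population_size = nrow(pop),
    metrics = metrics, costs = costs,
    initial_population = pop,
    final_state = if (is.null(raw)) NULL else raw$final_state,
    n_released = if (is.null(raw)) 0L else raw$n_released,
    n_rearrested = if (is.null(raw)) 0L else raw$n_rearrested,
    events = events
  ), class = "spmi_run_result")
  res$summary <- summarize_run(res)
  res
}

#' End-of-run summary statistics
#'
#' @param result An `spmi_run_result`.
#' @return Named list of headline metrics: annualized event counts, mean
#'   shares, realized attendance, recidivism, and total costs by category.
#' @export
summarize_run <- function(result) {
  m <- result$metrics
  co <- result$costs
  if (nrow(m) == 0L) {
    return(list(n_weeks = 0L, population = result$population_size))
  }
  years <- nrow(m) / 52
  cost_total <- function(cat) {
    sum(co[[paste0(cat, "_patient")]]) + sum(co[[paste0(cat, "_third_party")]])
  }
  totals <- vapply(.cost_categories, cost_total, 0)
  list(
    n_weeks = nrow(m),
    population = result$population_size,
    annual_crises = sum(m$crises) / years,
    annual_hospitalizations = sum(m$hospital_admissions) / years,
    annual_arrests = sum(m$arrests) / years,
    annual_homelessness_entries = sum(m$homeless_entries) / years,
    annual_suicides = sum(m$suicides) / years,
    adherence_rate = mean(m$on_medication / m$alive),
    on_medication_share = mean(m$on_medication / m$alive),
    lost_share = mean(m$lost_to_system / m$alive),
    private_residence_mean = mean(m$env_private_residence),
    private_residence_share = mean(m$env_private_residence / m$alive),
    homeless_share = mean(m$env_homeless / m$alive),
    attendance_rate = sum(m$appts_kept) / max(1, sum(m$appts_scheduled)),
    recidivism_rate = if (result$n_released > 0)
      result$n_rearrested / result$n_released else NA_real_,
    mean_mental_health = mean(m$mean_mental_health),
    mean_physical_health = mean(m$mean_physical_health),
    cost_totals = as.list(totals),
    total_cost = sum(totals),
    incarceration_cost = totals[["incarceration"]],
    hospitalization_cost = totals[["hospitalization"]]
  )
}

#' @export
print.spmi_run_result <- function(x, ...) {
  s <- x$summary
  cat("<spmi_run_result>", x$population_size, "patients x", x$n_weeks,
      "weeks (seed", x$seed, ")\n")
  if (x$n_weeks > 0) {
    cat(sprintf("  annual crises %.1f | hospitalizations %.1f | arrests %.1f | suicides %.2f\n",
                s$annual_crises, s$annual_hospitalizations, s$annual_arrests,
                s$annual_suicides))
    cat(sprintf("  on medication %.1f%% | lost to system %.1f%% | attendance %.1f%%\n",
                100 * s$on_medication_share, 100 * s$lost_share,
                100 * s$attendance_rate))
    cat(sprintf("  total cost %.0f (incarceration %.0f, hospitalization %.0f)\n",
                s$total_cost, s$incarceration_cost, s$hospitalization_cost))
  }
  invisible(x)
}

#' Run replicated simulations and pool the summaries
#'
#' Seeds are derived deterministically from `base_seed` (consecutive
#' integers), which also provides common random numbers when the same
#' `base_seed` is reused across configurations.
#'
#' @param cfg A validated `spmi_config`.
#' @param n Number of replications (default: the profile's
#'   `system.n_replications`).
#' @param base_seed First seed.
#' @param keep_runs Keep the individual `spmi_run_result`s (memory!).
#' @return List with `pooled` (a data frame of per-metric mean, sd, se, n)
#'   and optionally `runs`.
#' @export
run_replications <- function(cfg, n = cfg$system$n_replications,
                             base_seed = cfg$system$seed, keep_runs = FALSE) {
  stopifnot(n >= 1)
  seeds <- as.integer(base_seed) + seq_len(n) - 1L
  runs <- vector("list", n)
  sums <- vector("list", n)
  for (i in seq_len(n)) {
    r <- run_simulation(cfg, seed = seeds[i])
    sums[[i]] <- .flatten_summary(r$summary)
    if (keep_runs) runs[[i]] <- r
  }
  keys <- names(sums[[1]])
  mat <- vapply(sums, function(s) as.numeric(s[keys]), numeric(length(keys)))
  mat <- matrix(mat, nrow = length(keys),
                dimnames = list(keys, NULL))
  pooled <- data.frame(
    metric = keys,
    mean = rowMeans(mat),
    sd = apply(mat, 1, sd),
    n = n, stringsAsFactors = FALSE)
  pooled$se <- if (n > 1) pooled$sd / sqrt(n) else NA_real_
  list(pooled = pooled, runs = if (keep_runs) runs else NULL,
       seeds = seeds)
}

.flatten_summary <- function(s) {
  s$cost_totals <- NULL
  out <- unlist(s)
  out[vapply(out, is.numeric, NA)]
}

#' Export a run to plain-text output files
#'
#' Writes the weekly metrics, the cost ledger, the event log (when the run
#' kept one) and a JSON manifest (profile hash, seed, package version)
#' sufficient to reproduce the run.
#'
#' @param result An `spmi_run_result`.
#' @param out_dir Output directory (created if needed).
#' @return Character vector of written file paths, invisibly.
#' @export
export_results <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) {
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  }
  paths <- c(
    metrics = file.path(out_dir, "weekly_metrics.csv"),
    costs = file.path(out_dir, "cost_ledger.csv"),
    manifest = file.path(out_dir, "manifest.json"))
  write.csv(result$metrics, paths[["metrics"]], row.names = FALSE)
  write.csv(result$costs, paths[["costs"]], row.names = FALSE)
  if (!is.null(result$events)) {
    paths <- c(paths, events = file.path(out_dir, "event_log.csv"))
    write.csv(result$events, paths[["events"]], row.names = FALSE)
  }
  manifest <- list(
    package = "spmiecosim",
    version = as.character(utils::packageVersion("spmiecosim")),
    config_hash = result$config_hash,
    seed = result$seed,
    n_weeks = result$n_weeks,
    population = result$population_size)
  jsonlite::write_json(manifest, paths[["manifest"]], auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(paths)
}
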