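#' Load and validate a simulation profile
#'
#' Reads a YAML profile describing every input of the ecosystem model --
#' the six input groups (system run control, patient population, treatment
#' plans/medicines, care providers, physical environments, law enforcement
#' and criminal justice) plus the two care-coordination levers, the
#' adherence state-chart weights and the score-dynamics coefficients -- and
#' validates every documented invariant before returning it.
#'
#' @param path Path to a YAML profile file.
#' @return A validated `spmi_config` object (a structured list).
#' @seealso [validate_config()], [default_profile_path()]
#' @export
load_config <- function(path) {
  if (!file.exists(path)) {
    stop("config file not found: ", path, call. = FALSE)
  }
  raw <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop("config parse failure in '", path, "': ", conditionMessage(e),
           call. = FALSE)
    }
  )
  cfg <- as_spmi_config(raw)
  v <- validate_config(cfg)
  if (nrow(v) > 0L) {
    stop("invalid config '", path, "':\n",
         paste0("  - ", v$field, ": ", v$constraint,
                " (observed ", v$value, ")", collapse = "\n"),
         call. = FALSE)
  }
  cfg
}

#' @rdname load_config
#' @param x A list with the profile structure (e.g. parsed YAML).
#' @export
as_spmi_config <- function(x) {
  stopifnot(is.list(x))
  structure(x, class = "spmi_config")
}

#' Path to the shipped default calibrated city profile
#' @return File path of the packaged default profile.
#' @export
default_profile_path <- function() {
  system.file("extdata", "default_profile.yaml", package = "spmiecosim",
              mustWork = TRUE)
}

#' Load the shipped default calibrated city profile
#' @return A validated `spmi_config`.
#' @export
load_default_profile <- function() {
  load_config(default_profile_path())
}

#' Serialize a profile back to YAML
#'
#' `load_config(save_config(cfg, p))` round-trips to an equal config.
#'
#' @param cfg An `spmi_config`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path, precision = 12L)
  invisible(path)
}

#' Stable hash of a profile
#'
#' MD5 of the canonical YAML serialization; recorded in run manifests so a
#' result can be matched to the exact profile that produced it.
#'
#' @param cfg An `spmi_config`.
#' @return A hex string.
#' @export
config_hash <- function(cfg) {
  tf <- tempfile(fileext = ".yaml")
  on.exit(unlink(tf), add = TRUE)
  writeLines(yaml::as.yaml(unclass(cfg), precision = 12L), tf)
  unname(tools::md5sum(tf))
}

#' @export
print.spmi_config <- function(x, ...) {
  cat("<spmi_config>", x$profile_name %||% "(unnamed profile)", "\n")
  cat("  patients:", x$patients$population_size,
      "| weeks:", x$system$run_length_weeks,
      "| replications:", x$system$n_replications, "\n")
  cat("  levers: handoff =", x$levers$handoff_success_rate,
      ", compliance =", x$levers$patient_appointment_compliance_rate,
      ", funding =", x$levers$funding_support_level, "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- accessors by dotted path ------------------------------------------------

#' Get or set a config entry by dotted path
#'
#' Paths address nested entries, e.g. `"levers.handoff_success_rate"` or
#' `"patients.crisis_onset_weekly.severe"`. List entries with an `id` field
#' (medicines, providers, environments) are addressed by id, e.g.
#' `"providers.cmhc.count"`.
#'
#' @param cfg An `spmi_config`.
#' @param path Dotted path string.
#' @param value Replacement value (for `config_set`).
#' @return `config_get` returns the entry; `config_set` returns the modified
#'   config (the input is unchanged).
#' @export
config_get <- function(cfg, path) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  node <- cfg
  for (k in keys) {
    node <- .config_child(node, k, path)
  }
  node
}

#' @rdname config_get
#' @export
config_set <- function(cfg, path, value) {
  keys <- strsplit(path, ".", fixed = TRUE)[[1]]
  cfg_un <- unclass(cfg)
  cfg_un <- .config_assign(cfg_un, keys, value, path)
  as_spmi_config(cfg_un)
}

.config_child <- function(node, key, path) {
  if (!is.null(names(node)) && key %in% names(node)) {
    return(node[[key]])
  }
  # unnamed list of records with id fields
  if (is.list(node) && is.null(names(node))) {
    ids <- vapply(node, function(r) r$id %||% "", "")
    hit <- which(ids == key)
    if (length(hit) == 1L) return(node[[hit]])
  }
  stop("config path not found: '", path, "' (missing '", key, "')",
       call. = FALSE)
}

.config_assign <- function(node, keys, value, path) {
  if (length(keys) == 0L) return(value)
  k <- keys[[1]]
  if (!is.null(names(node)) && k %in% names(node)) {
    node[[k]] <- .config_assign(node[[k]], keys[-1], value, path)
    return(node)
  }
  if (is.list(node) && is.null(names(node))) {
    ids <- vapply(node, function(r) r$id %||% "", "")
    hit <- which(ids == k)
    if (length(hit) == 1L) {
      node[[hit]] <- .config_assign(node[[hit]], keys[-1], value, path)
      return(node)
    }
  }
  stop("config path not found: '", path, "' (missing '", k, "')",
       call. = FALSE)
}

# --- validation --------------------------------------------------------------

#' Validate a profile against every schema invariant
#'
#' Returns violations instead of raising: an empty data frame means the
#' profile is valid. Each violation names the offending field path, the
#' observed value and the constraint it breaks.
#'
#' @param cfg An `spmi_config` (or plain list with the same structure).
#' @return A data frame with columns `field`, `value`, `constraint`.
#' @export
validate_config <- function(cfg) {
  v <- list()
  add <- function(field, value, constraint) {
    v[[length(v) + 1L]] <<- data.frame(
      field = field, value = paste(format(value), collapse = ","),
      constraint = constraint, stringsAsFactors = FALSE)
  }
  need <- function(field, ok, value, constraint) {
    if (!isTRUE(ok)) add(field, value, constraint)
    isTRUE(ok)
  }
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  prob1 <- function(field, x) {
    need(field, num1(x) && x >= 0 && x <= 1, x, "must be a probability in [0,1]")
  }
  catdist <- function(field, x, names_expected = NULL) {
    if (!need(field, is.list(x) || (is.numeric(x) && !is.null(names(x))),
              class(x), "must be a named categorical distribution")) {
      return(invisible(NULL))
    }
    p <- unlist(x)
    if (!is.null(names_expected) &&
        !need(field, setequal(names(p), names_expected), names(p),
              paste("categories must be exactly:",
                    paste(names_expected, collapse = ", ")))) {
      return(invisible(NULL))
    }
    for (nm in names(p)) prob1(paste0(field, ".", nm), p[[nm]])
    need(field, abs(sum(p) - 1) <= 1e-9, sum(p),
         "probabilities must sum to 1 (tolerance 1e-9)")
  }
  distspec <- function(field, x, kinds = c("normal", "beta", "lognormal", "point")) {
    if (!need(field, is.list(x) && !is.null(x$dist), x,
              "must be a distribution spec with a 'dist' entry")) return(invisible(NULL))
    if (!need(field, x$dist %in% kinds, x$dist,
              paste("dist must be one of:", paste(kinds, collapse = ", ")))) {
      return(invisible(NULL))
    }
    pars <- switch(x$dist,
      normal = c("mean", "sd"), beta = c("shape1", "shape2"),
      lognormal = c("meanlog", "sdlog"), point = "value")
    for (p in pars) {
      need(paste0(field, ".", p), num1(x[[p]] %||% NA_real_), x[[p]] %||% NA,
           "required numeric distribution parameter")
    }
    if (x$dist == "normal") need(paste0(field, ".sd"), num1(x$sd) && x$sd >= 0,
                                 x$sd, "sd must be >= 0")
    if (x$dist == "beta") {
      for (p in pars) need(paste0(field, ".", p),
                           num1(x[[p]]) && x[[p]] > 0, x[[p]], "must be > 0")
    }
  }

  for (grp in c("system", "patients", "medicines", "providers", "environments",
                "transitions", "justice", "levers", "adherence_chart",
                "dynamics", "economics")) {
    need(grp, !is.null(cfg[[grp]]), NULL, "required config group is missing")
  }
  if (length(v) > 0L) return(do.call(rbind, v))

  sys <- cfg$system
  need("system.run_length_weeks",
       num1(sys$run_length_weeks) && sys$run_length_weeks >= 0 &&
         sys$run_length_weeks == floor(sys$run_length_weeks),
       sys$run_length_weeks, "must be a nonnegative integer number of weeks")
  need("system.n_replications",
       num1(sys$n_replications) && sys$n_replications >= 1,
       sys$n_replications, "must be >= 1")

  pa <- cfg$patients
  need("patients.population_size",
       num1(pa$population_size) && pa$population_size >= 0 &&
         pa$population_size == floor(pa$population_size),
       pa$population_size, "must be a nonnegative integer")
  catdist("patients.age_bands", pa$age_bands)
  catdist("patients.diagnoses", pa$diagnoses)
  catdist("patients.initial_environment", pa$initial_environment)
  if (!is.null(pa$initial_environment)) {
    need("patients.initial_environment",
         all(names(unlist(pa$initial_environment)) %in% .envs_stable),
         names(unlist(pa$initial_environment)),
         "initial environments must be stable environments")
  }
  distspec("patients.initial_mental_health", pa$initial_mental_health)
  distspec("patients.mh_floor", pa$mh_floor)
  distspec("patients.initial_physical_health", pa$initial_physical_health)
  distspec("patients.ph_decline_factor", pa$ph_decline_factor)
  distspec("patients.stress_base", pa$stress_base)
  distspec("patients.family_support", pa$family_support)
  distspec("patients.initial_financial_resources", pa$initial_financial_resources)
  mh_mean <- switch(pa$initial_mental_health$dist %||% "", point = pa$initial_mental_health$value,
                    normal = pa$initial_mental_health$mean, NULL)
  fl_mean <- switch(pa$mh_floor$dist %||% "", point = pa$mh_floor$value,
                    normal = pa$mh_floor$mean, NULL)
  if (!is.null(mh_mean) && !is.null(fl_mean)) {
    need("patients.mh_floor", fl_mean <= mh_mean, fl_mean,
         "mh_floor location must not exceed initial mental health location")
  }
  for (f in c("substance_abuse_initial", "substance_start_weekly",
              "substance_stop_weekly", "employed_initial",
              "employment_gain_weekly", "employment_loss_weekly",
              "initial_on_medication", "plan_transfer_weekly")) {
    prob1(paste0("patients.", f), pa[[f]])
  }
  for (f in c("income_employed_weekly", "benefits_weekly")) {
    need(paste0("patients.", f), num1(pa[[f]]) && pa[[f]] >= 0, pa[[f]],
         "must be a nonnegative weekly amount")
  }
  need("patients.employment_min_mh",
       num1(pa$employment_min_mh) && pa$employment_min_mh >= 1 &&
         pa$employment_min_mh <= 100,
       pa$employment_min_mh, "must be a score in [1,100]")
  pl <- pa$plan
  need("patients.plan.cmhc_every",
       num1(pl$cmhc_every %||% NA_real_) && pl$cmhc_every >= 1, pl$cmhc_every,
       "appointment interval must be >= 1 week")
  need("patients.plan.caseworker_every",
       num1(pl$caseworker_every %||% NA_real_) && pl$caseworker_every >= 1,
       pl$caseworker_every, "appointment interval must be >= 1 week")
  prob1("patients.plan.p_lai", pl$p_lai %||% NA_real_)
  prob1("patients.plan.p_no_medicine", pl$p_no_medicine %||% NA_real_)
  catdist("patients.propensity_to_commit_crime", pa$propensity_to_commit_crime,
          NULL)
  need("patients.propensity_to_commit_crime",
       setequal(names(unlist(pa$propensity_to_commit_crime)), .mh_categories),
       names(unlist(pa$propensity_to_commit_crime)),
       "must give one weekly probability per mental-health category")
  # per-category weekly probabilities need not sum to 1; undo the sum check
  catprobs <- function(field, x) {
    p <- unlist(x)
    need(field, setequal(names(p), .mh_categories), names(p),
         "must give one weekly probability per mental-health category")
    for (nm in names(p)) prob1(paste0(field, ".", nm), p[[nm]])
  }
  v <- Filter(function(r) !(r$field == "patients.propensity_to_commit_crime" &&
                              grepl("sum to 1", r$constraint)), v)
  catprobs("patients.crisis_onset_weekly", pa$crisis_onset_weekly)
  catdist("patients.crisis_outcomes", pa$crisis_outcomes, .crisis_outcomes)

  meds <- cfg$medicines
  ids <- vapply(meds, function(m) m$id %||% "", "")
  need("medicines", length(meds) >= 1, length(meds), "at least one medicine required")
  if (anyDuplicated(ids)) {
    add("medicines.id", ids[duplicated(ids)][1], "medicine ids must be unique")
  }
  for (m in meds) {
    f <- paste0("medicines.", m$id)
    need(paste0(f, ".cost_to_patient_factor"),
         num1(m$cost_to_patient_factor) && m$cost_to_patient_factor %in% 0:5,
         m$cost_to_patient_factor, "cost-to-patient factor must be in {0,...,5}")
    need(paste0(f, ".refill_frequency_weeks"),
         num1(m$refill_frequency_weeks) && m$refill_frequency_weeks >= 1,
         m$refill_frequency_weeks, "refill frequency must be >= 1 week")
    need(paste0(f, ".system_cost_per_week"),
         num1(m$system_cost_per_week) && m$system_cost_per_week >= 0,
         m$system_cost_per_week, "must be >= 0")
    for (s in c("short_term_side_effect_severity", "long_term_side_effect_severity")) {
      need(paste0(f, ".", s), num1(m[[s]]) && m[[s]] >= 0, m[[s]], "must be >= 0")
    }
  }
  lai <- vapply(meds, function(m) isTRUE(m$is_long_acting_injectable), NA)
  need("medicines", any(lai), sum(lai),
       "profile must include a long-acting injectable medicine")
  need("medicines", any(!lai), sum(!lai),
       "profile must include a non-LAI medicine")

  provs <- cfg$providers
  pids <- vapply(provs, function(p) p$id %||% "", "")
  if (anyDuplicated(pids)) {
    add("providers.id", pids[duplicated(pids)][1], "provider ids must be unique")
  }
  ptypes <- vapply(provs, function(p) p$provider_type %||% "", "")
  need("providers", setequal(ptypes, .provider_types) &&
         !anyDuplicated(ptypes), ptypes,
       paste("exactly one provider of each type required:",
             paste(.provider_types, collapse = ", ")))
  for (p in provs) {
    f <- paste0("providers.", p$id)
    need(paste0(f, ".count"), num1(p$count) && p$count >= 0 &&
           p$count == floor(p$count), p$count, "count must be a nonnegative integer")
    need(paste0(f, ".capacity_per_week"),
         num1(p$capacity_per_week) && p$capacity_per_week >= 0,
         p$capacity_per_week, "capacity must be >= 0")
    prob1(paste0(f, ".lai_probability"), p$lai_probability)
    need(paste0(f, ".cost_to_patient_factor"),
         num1(p$cost_to_patient_factor) && p$cost_to_patient_factor %in% 0:5,
         p$cost_to_patient_factor, "cost-to-patient factor must be in {0,...,5}")
    need(paste0(f, ".third_party_cost"),
         num1(p$third_party_cost) && p$third_party_cost >= 0,
         p$third_party_cost, "must be >= 0")
  }

  envs <- cfg$environments
  eids <- vapply(envs, function(e) e$id %||% "", "")
  if (anyDuplicated(eids)) {
    add("environments.id", eids[duplicated(eids)][1],
        "environment ids must be unique")
  }
  need("environments", setequal(eids, .envs_all), eids,
       paste("environment ids must be exactly:", paste(.envs_all, collapse = ", ")))
  for (e in envs) {
    f <- paste0("environments.", e$id)
    episodic <- e$id %in% c("hospital_inpatient", "correctional_facility")
    need(paste0(f, ".stability_flag"),
         isTRUE(e$stability_flag) == !episodic, e$stability_flag,
         "stability flag must be true exactly for non-episodic environments")
    prob1(paste0(f, ".probability_of_being_located"),
          e$probability_of_being_located)
    need(paste0(f, ".capacity"),
         num1(e$capacity) && (e$capacity == -1 || e$capacity >= 0),
         e$capacity, "capacity must be -1 (unbounded) or >= 0")
    for (cc in c("weekly_cost_patient", "weekly_cost_third_party")) {
      need(paste0(f, ".", cc), num1(e[[cc]]) && e[[cc]] >= 0, e[[cc]],
           "must be >= 0")
    }
    if (episodic) {
      los <- e$length_of_stay_weeks
      ok <- is.list(los) && num1(los$mean %||% NA_real_) &&
        num1(los$min %||% NA_real_) && los$min >= 1 && los$mean >= los$min
      need(paste0(f, ".length_of_stay_weeks"), ok, unlist(los),
           "episodic environments need length of stay with 1 <= min <= mean")
    }
  }

  tr <- cfg$transitions
  for (env in .envs_stable) {
    rows <- tr[[env]]
    if (!need(paste0("transitions.", env), is.list(rows), class(rows),
              "transition rows required for every stable environment")) next
    for (cat in .mh_categories) {
      f <- paste0("transitions.", env, ".", cat)
      row <- rows[[cat]]
      if (!need(f, !is.null(row), NULL, "transition row required")) next
      p <- unlist(row)
      need(f, all(names(p) %in% .envs_stable), names(p),
           "destinations must be stable environments")
      for (nm in names(p)) prob1(paste0(f, ".", nm), p[[nm]])
      need(f, abs(sum(p) - 1) <= 1e-9, sum(p),
           "transition row must sum to 1 (tolerance 1e-9)")
    }
  }

  ju <- cfg$justice
  catdist("justice.initial_criminal_history", ju$initial_criminal_history,
          c("none", "prior_misdemeanor", "prior_felony"))
  prob1("justice.cit_officer_probability", ju$cit_officer_probability)
  catdist("justice.crime_degrees", ju$crime_degrees, c("misdemeanor", "felony"))
  for (d in c("misdemeanor", "felony")) {
    s <- ju$sentence_weeks[[d]]
    ok <- is.list(s) && num1(s$mean %||% NA_real_) && num1(s$min %||% NA_real_) &&
      s$min >= 1 && s$mean >= s$min
    need(paste0("justice.sentence_weeks.", d), ok, unlist(s),
         "sentence duration needs 1 <= min <= mean")
  }
  prob1("justice.jail_diversion_entry_probability",
        ju$jail_diversion_entry_probability)
  need("justice.diversion_weeks", num1(ju$diversion_weeks) &&
         ju$diversion_weeks >= 1, ju$diversion_weeks, "must be >= 1 week")
  catdist("justice.discharge_location", ju$discharge_location)
  need("justice.discharge_location",
       all(names(unlist(ju$discharge_location)) %in% .envs_stable),
       names(unlist(ju$discharge_location)),
       "discharge locations must be stable environments")

  le <- cfg$levers
  prob1("levers.handoff_success_rate", le$handoff_success_rate)
  prob1("levers.patient_appointment_compliance_rate",
        le$patient_appointment_compliance_rate)
  prob1("levers.outreach_probability", le$outreach_probability %||% 0)
  need("levers.funding_support_level",
       num1(le$funding_support_level) && le$funding_support_level >= 0,
       le$funding_support_level, "must be >= 0")

  ac <- cfg$adherence_chart
  w <- unlist(ac$factor_weights)
  need("adherence_chart.factor_weights", setequal(names(w), .adherence_factors),
       names(w), paste("weights required for factors:",
                       paste(.adherence_factors, collapse = ", ")))
  need("adherence_chart", num1(ac$stop_threshold) && num1(ac$start_threshold) &&
         ac$stop_threshold <= ac$start_threshold,
       c(ac$stop_threshold, ac$start_threshold),
       "stop_threshold must be <= start_threshold")

  dy <- cfg$dynamics
  for (f in c("medication_mh_effect", "untreated_decline", "crisis_mh_shock",
              "stress_mh_coef",
              "support_mh_coef", "mh_ph_coupling", "ph_mh_coupling",
              "side_effect_ph_coef", "financial_strain_stress",
              "stress_noise_sd")) {
    need(paste0("dynamics.", f), num1(dy[[f]]), dy[[f]],
         "required numeric coefficient")
  }
  need("dynamics.stress_noise_sd", num1(dy$stress_noise_sd) &&
         dy$stress_noise_sd >= 0, dy$stress_noise_sd, "must be >= 0")
  need("dynamics.untreated_decline", num1(dy$untreated_decline) &&
         dy$untreated_decline >= 0, dy$untreated_decline, "must be >= 0")

  ec <- cfg$economics
  need("economics.resources_ref", num1(ec$resources_ref) && ec$resources_ref > 0,
       ec$resources_ref, "must be > 0")
  need("economics.access_floor", num1(ec$access_floor) && ec$access_floor >= 0 &&
         ec$access_floor <= 1, ec$access_floor, "must be in [0,1]")
  for (f in c("copay_per_factor_medication", "copay_per_factor_visit",
              "low_resources_threshold")) {
    need(paste0("economics.", f), num1(ec[[f]]) && ec[[f]] >= 0, ec[[f]],
         "must be >= 0")
  }

  if (length(v) == 0L) {
    return(data.frame(field = character(), value = character(),
                      constraint = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, v)
}

# --- funding lever -----------------------------------------------------------

#' Derive a profile under a different funding support level
#'
#' Funding support scales the supply side of the system: provider counts are
#' scaled linearly (rounded down, never below zero) and the cost-to-patient
#' factors of medicines and provider services shift by `round(log2(level))`
#' in the opposite direction (more funding lowers the patient's cost
#' barrier), clamped to the 0--5 factor scale. A level of 1 returns an
#' identical profile; the input is never modified.
#'
#' @param cfg An `spmi_config`.
#' @param level Nonnegative scalar funding support level (1 = current state).
#' @return A derived `spmi_config` with `levers.funding_support_level = level`.
#' @export
apply_funding_level <- function(cfg, level) {
  if (!is.numeric(level) || length(level) != 1L || is.na(level) || level < 0) {
    stop("funding level must be a nonnegative scalar", call. = FALSE)
  }
  shift <- round(log2(max(level, 2^-10)))
  clampf <- function(f) max(0L, min(5L, as.integer(round(f - shift))))
  out <- unclass(cfg)
  out$providers <- lapply(out$providers, function(p) {
    p$count <- max(0L, as.integer(floor(p$count * level)))
    p$cost_to_patient_factor <- clampf(p$cost_to_patient_factor)
    p
  })
  out$medicines <- lapply(out$medicines, function(m) {
    m$cost_to_patient_factor <- clampf(m$cost_to_patient_factor)
    m
  })
  out$levers$funding_support_level <- level
  as_spmi_config(out)
}
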