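# Weekly per-patient dynamics: the reference (single-patient) form of the
# update that the compiled engine applies population-wide. The engine in
# src/engine.cpp implements exactly these formulas; tests hold the two in
# agreement on forced (probability 0/1) scenarios.

.env_by_id <- function(cfg, id) {
  for (e in cfg$environments) if (e$id == id) return(e)
  stop("unknown environment id: ", id, call. = FALSE)
}

.med_by_id <- function(cfg, id) {
  if (is.null(id) || is.na(id)) return(NULL)
  for (m in cfg$medicines) if (m$id == id) return(m)
  stop("unknown medicine id: ", id, call. = FALSE)
}

.provider_by_type <- function(cfg, type) {
  for (p in cfg$providers) if (p$provider_type == type) return(p)
  stop("unknown provider type: ", type, call. = FALSE)
}

#' Weekly stress level of a patient
#'
#' Stress combines the patient's trait level, the stress of the current
#' environment, financial strain when resources fall below the configured
#' threshold, and (in the stochastic engine) a small weekly disturbance;
#' clamped to `[0, 1]`.
#'
#' @param patient Patient record with `stress_base`, `financial_resources`.
#' @param cfg An `spmi_config`.
#' @param environment_id Current environment id.
#' @param noise Optional additive disturbance (default 0, deterministic).
#' @return Stress in `[0, 1]`.
#' @export
weekly_stress <- function(patient, cfg, environment_id = patient$environment,
                          noise = 0) {
  env <- .env_by_id(cfg, as.character(environment_id))
  strain <- cfg$dynamics$financial_strain_stress *
    (patient$financial_resources < cfg$economics$low_resources_threshold)
  pmin(1, pmax(0, patient$stress_base + env$stress_level + strain + noise))
}

#' Medication-adherence factor score
#'
#' The adherence state chart transitions on a numerical score to which each
#' factor contributes a signed influence: stress, active substance abuse,
#' medication side-effect severity and cost push the score down; family
#' support, an active long-acting injectable and recent provider contact
#' push it up.
#'
#' @param factors Named list/vector of factor values (names as in the
#'   `adherence_chart.factor_weights` block).
#' @param weights Named weights from the adherence chart.
#' @return The scalar adherence score.
#' @export
adherence_score <- function(factors, weights) {
  w <- unlist(weights)
  x <- unlist(factors)[names(w)]
  sum(w * as.numeric(x))
}

#' One step of the medication-adherence state chart
#'
#' Computes the adherence score from the supplied context and applies the
#' hysteresis rule: a patient on medication whose score falls strictly below
#' `stop_threshold` stops taking it (unless a long-acting injectable is
#' still active, which suppresses the off-transition until the injection
#' interval lapses); a patient off medication whose score rises strictly
#' above `start_threshold` resumes (unless lost to the system). Patients
#' with no medicine in their plan are unaffected.
#'
#' @param patient Patient record.
#' @param chart The `adherence_chart` config block.
#' @param context List with `stress`, `recent_provider_contact` (logical),
#'   `side_effect_severity`, `cost_to_patient_factor`.
#' @return The patient with updated `on_medication` and an
#'   `adherence_score` field.
#' @export
adherence_step <- function(patient, chart, context) {
  if (is.null(patient$medicine) || is.na(patient$medicine)) {
    return(patient)
  }
  lai_active <- isTRUE(patient$lai_weeks_left > 0)
  sc <- adherence_score(
    list(stress = context$stress,
         substance_abuse = as.numeric(isTRUE(patient$substance_abuse)),
         side_effect_severity = context$side_effect_severity,
         cost_to_patient_factor = context$cost_to_patient_factor,
         family_support = patient$family_support,
         lai_active = as.numeric(lai_active),
         recent_provider_contact = as.numeric(isTRUE(context$recent_provider_contact))),
    chart$factor_weights)
  patient$adherence_score <- sc
  if (isTRUE(patient$on_medication)) {
    if (sc < chart$stop_threshold && !lai_active) {
      patient$on_medication <- FALSE
    }
  } else if (sc > chart$start_threshold && !isTRUE(patient$lost_to_system)) {
    patient$on_medication <- TRUE
  }
  patient
}

#' Draw this week's critical outcome for a patient
#'
#' Critical outcomes open the weekly decision sequence: a mental-health
#' crisis (probability per week set by the patient's coarse mental-health
#' category), starting or stopping substance abuse, and finding or losing
#' employment. When several fire the highest-priority one applies
#' (crisis > substance abuse > employment). A crime draw (the non-crisis
#' arrest channel, also category-conditioned) is treated at crisis priority
#' below crisis itself.
#'
#' @param patient Patient record.
#' @param cfg An `spmi_config`.
#' @return A list with `kind` in `crisis`, `crime`, `substance_abuse_start`,
#'   `substance_abuse_stop`, `employment_found`, `employment_lost`, `none`.
#' @export
draw_critical_outcomes <- function(patient, cfg) {
  pa <- cfg$patients
  cat <- as.character(mh_category(patient$mental_health, coarse = TRUE))
  if (runif(1) < pa$crisis_onset_weekly[[cat]]) {
    return(list(kind = "crisis"))
  }
  if (runif(1) < pa$propensity_to_commit_crime[[cat]]) {
    return(list(kind = "crime"))
  }
  if (isTRUE(patient$substance_abuse)) {
    if (runif(1) < pa$substance_stop_weekly) {
      return(list(kind = "substance_abuse_stop"))
    }
  } else if (runif(1) < pa$substance_start_weekly) {
    return(list(kind = "substance_abuse_start"))
  }
  if (isTRUE(patient$employed)) {
    if (runif(1) < pa$employment_loss_weekly) {
      return(list(kind = "employment_lost"))
    }
  } else if (patient$mental_health >= pa$employment_min_mh &&
             runif(1) < pa$employment_gain_weekly) {
    return(list(kind = "employment_found"))
  }
  list(kind = "none")
}

#' Weekly mental-health score update
#'
#' `score' = clamp(score + medication effect + provider-contact effect +
#' environment effect - untreated decline (applied iff the patient is off
#' medication and had no provider contact this week) - stress effect +
#' support effect + coupling x (physical - mental)/100 + crisis shock,
#' mh_floor, 100)`. The per-patient floor captures that untreated patients
#' decline to a certain level and no further.
#'
#' @param patient Patient record.
#' @param cfg An `spmi_config`.
#' @param events List with `provider_contact` (logical),
#'   `provider_mh_effect` (summed per-visit effects), `environment_mh_effect`,
#'   `stress`, and optionally `crisis_shock` (a negative delta when a crisis
#'   fired this week).
#' @return The updated score.
#' @export
update_mental_health <- function(patient, cfg, events) {
  dy <- cfg$dynamics
  untreated <- !isTRUE(patient$on_medication) && !isTRUE(events$provider_contact)
  s <- patient$mental_health +
    dy$medication_mh_effect * isTRUE(patient$on_medication) +
    (events$provider_mh_effect %||% 0) +
    (events$environment_mh_effect %||% 0) -
    dy$untreated_decline * untreated -
    dy$stress_mh_coef * (events$stress %||% 0) +
    dy$support_mh_coef * patient$family_support +
    dy$mh_ph_coupling * (patient$physical_health - patient$mental_health) / 100 +
    (events$crisis_shock %||% 0)
  pmin(100, pmax(patient$mh_floor, s))
}

#' Weekly physical-health score update
#'
#' `score' = clamp(score + decline factor + environment effect - side-effect
#' burden (long-term severity of the current medicine, while taken) +
#' coupling x (mental - physical)/100, 1, 100)`; the coupling uses the
#' pre-update mental score.
#'
#' @inheritParams update_mental_health
#' @param events List with `environment_ph_effect`.
#' @return The updated score.
#' @export
update_physical_health <- function(patient, cfg, events) {
  dy <- cfg$dynamics
  med <- .med_by_id(cfg, patient$medicine)
  se <- if (!is.null(med) && isTRUE(patient$on_medication)) {
    dy$side_effect_ph_coef * med$long_term_side_effect_severity
  } else 0
  s <- patient$physical_health +
    patient$ph_decline_factor +
    (events$environment_ph_effect %||% 0) -
    se +
    dy$ph_mh_coupling * (patient$mental_health - patient$physical_health) / 100
  pmin(100, pmax(1, s))
}

#' Weekly environment transition for a patient in a stable environment
#'
#' Draws the destination from the transition row of the current environment
#' and the patient's coarse mental-health category. A capacity-limited
#' destination that is full redirects to its overflow destination
#' (homeless, for housing). Episodic environments (hospital, correctional
#' facility) are never entered this way; patients mid-stay
#' (`environment_weeks_remaining > 0`) do not transition.
#'
#' @param patient Patient record (in a stable environment).
#' @param cfg An `spmi_config`.
#' @param occupancy Named integer vector of current occupancy per
#'   environment (used for capacity checks); `NULL` skips the check.
#' @return The destination environment id.
#' @export
transition_environment <- function(patient, cfg, occupancy = NULL) {
  env_id <- as.character(patient$environment)
  if (!env_id %in% .envs_stable) {
    stop("transition_environment applies to stable environments; '",
         env_id, "' is episodic", call. = FALSE)
  }
  wr <- patient$environment_weeks_remaining
  if (!is.null(wr) && !is.na(wr) && wr > 0) {
    return(env_id)
  }
  cat <- as.character(mh_category(patient$mental_health, coarse = TRUE))
  row <- cfg$transitions[[env_id]][[cat]]
  if (is.null(row)) {
    stop("missing transition row for environment '", env_id,
         "', category '", cat, "'", call. = FALSE)
  }
  p <- unlist(row)
  dest <- names(p)[sample.int(length(p), 1L, prob = p)]
  if (!is.null(occupancy) && dest != env_id) {
    e <- .env_by_id(cfg, dest)
    if (e$capacity >= 0 && occupancy[[dest]] >= e$capacity) {
      dest <- e$overflow_destination %||% "homeless"
    }
  }
  dest
}
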