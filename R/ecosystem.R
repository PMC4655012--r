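# Shared-resource side of the weekly update: provider capacity and
# appointments, referral handoffs, crisis resolution and the
# criminal-justice pathway. Reference (single-patient) form of the logic the
# compiled engine applies population-wide.

#' Create a fresh weekly ecosystem state
#'
#' Tracks remaining weekly capacity per provider type (count x capacity per
#' week) and occupancy per environment. Weekly provider capacity is renewed
#' with [reset_week()].
#'
#' @param cfg An `spmi_config`.
#' @param population Optional population data frame used to initialise
#'   environment occupancy.
#' @return An environment of class `spmi_ecosystem_state`.
#' @export
new_ecosystem_state <- function(cfg, population = NULL) {
  st <- new.env(parent = emptyenv())
  st$capacity_week <- vapply(
    setNames(.provider_types, .provider_types),
    function(t) {
      p <- .provider_by_type(cfg, t)
      p$count * p$capacity_per_week
    }, 0)
  st$capacity_left <- st$capacity_week
  st$occupancy <- setNames(rep(0L, length(.envs_all)), .envs_all)
  if (!is.null(population) && nrow(population) > 0L) {
    tab <- table(population$environment)
    st$occupancy[names(tab)] <- as.integer(tab)
  }
  st$week <- 1L
  class(st) <- c("spmi_ecosystem_state", "environment")
  st
}

#' @rdname new_ecosystem_state
#' @param state An `spmi_ecosystem_state`.
#' @export
reset_week <- function(state) {
  state$capacity_left <- state$capacity_week
  state$week <- state$week + 1L
  invisible(state)
}

# a renewed treatment plan comes with an active prescription
.renew_prescription <- function(patient, cfg) {
  if (is.null(patient$medicine) || is.na(patient$medicine)) {
    oral <- Filter(function(m) !isTRUE(m$is_long_acting_injectable),
                   cfg$medicines)[[1]]
    patient$medicine <- oral$id
  }
  patient$on_medication <- TRUE
  med <- .med_by_id(cfg, patient$medicine)
  if (isTRUE(med$is_long_acting_injectable)) {
    patient$lai_weeks_left <- med$refill_frequency_weeks
  }
  patient
}

.move_occupancy <- function(state, from, to) {
  if (!is.null(from) && !is.na(from)) {
    state$occupancy[[from]] <- state$occupancy[[from]] - 1L
  }
  if (!is.null(to) && !is.na(to)) {
    state$occupancy[[to]] <- state$occupancy[[to]] + 1L
  }
  invisible(state)
}

#' Attempt a scheduled appointment
#'
#' Attendance requires the patient to show up -- probability
#' `patient_appointment_compliance_rate x access_factor(provider cost
#' factor, resources)` -- and the provider to have weekly capacity left. An
#' attended appointment consumes one capacity unit, counts as provider
#' contact (feeding the adherence chart and the mental-health update),
#' accrues the service's costs, and with the facility's `lai_probability`
#' switches the plan's medicine to the long-acting injectable equivalent.
#'
#' @param patient Patient record (engaged, with this appointment due).
#' @param provider_type One of the four provider types.
#' @param cfg An `spmi_config`.
#' @param state An `spmi_ecosystem_state`.
#' @return List with `attended` (logical), `capacity_blocked` (logical),
#'   `patient` (possibly with medicine switched to the LAI), `provider_id`,
#'   `patient_cost`, `third_party_cost`, `mh_effect`.
#' @export
attempt_appointment <- function(patient, provider_type, cfg, state) {
  prov <- .provider_by_type(cfg, provider_type)
  p_att <- cfg$levers$patient_appointment_compliance_rate *
    access_factor(prov$cost_to_patient_factor, patient$financial_resources,
                  cfg$economics)
  out <- list(attended = FALSE, capacity_blocked = FALSE, patient = patient,
              provider_id = prov$id, patient_cost = 0, third_party_cost = 0,
              mh_effect = 0)
  if (runif(1) >= p_att) {
    return(out)
  }
  if (state$capacity_left[[provider_type]] < 1) {
    out$capacity_blocked <- TRUE
    return(out)
  }
  state$capacity_left[[provider_type]] <- state$capacity_left[[provider_type]] - 1
  out$attended <- TRUE
  out$patient_cost <- prov$cost_to_patient_factor *
    cfg$economics$copay_per_factor_visit
  out$third_party_cost <- prov$third_party_cost
  out$mh_effect <- prov$mh_effect_per_visit
  if (!is.null(patient$medicine) && !is.na(patient$medicine) &&
      runif(1) < prov$lai_probability) {
    lai <- Filter(function(m) isTRUE(m$is_long_acting_injectable), cfg$medicines)[[1]]
    out$patient$medicine <- lai$id
    out$patient$lai_weeks_left <- lai$refill_frequency_weeks
  }
  med <- .med_by_id(cfg, out$patient$medicine)
  if (!is.null(med) && isTRUE(med$is_long_acting_injectable) &&
      isTRUE(out$patient$on_medication)) {
    out$patient$lai_weeks_left <- med$refill_frequency_weeks  # re-injection
  }
  out
}

#' Refer a patient between providers (the handoff)
#'
#' A transfer -- a hospital discharge, a jail release, or re-engagement of a
#' lost patient after crisis stabilization -- succeeds with probability
#' `handoff_success_rate x probability_of_being_located(current
#' environment)`. On failure the patient becomes lost to the system: no
#' appointments and no refills until re-engaged through a later crisis
#' resolution (or configured outreach).
#'
#' @param patient Patient record.
#' @param cfg An `spmi_config`.
#' @return List with `success` (logical) and the updated `patient`
#'   (`lost_to_system` set accordingly).
#' @export
refer_patient <- function(patient, cfg) {
  env <- .env_by_id(cfg, as.character(patient$environment))
  p <- cfg$levers$handoff_success_rate * env$probability_of_being_located
  success <- runif(1) < p
  patient$lost_to_system <- !success
  list(success = success, patient = patient)
}

#' Resolve a mental-health crisis
#'
#' The crisis outcome is drawn from the configured distribution:
#' hospitalization admits the patient to the inpatient environment with a
#' drawn length of stay (admission and bed capacity permitting; if the
#' hospital cannot admit, the crisis is handled as a stabilization);
#' arrest enters the criminal-justice pathway ([process_arrest()]);
#' homelessness moves the patient to the homeless environment; suicide
#' removes the patient permanently; stabilization is a crisis stabilization
#' unit contact with no environment change. A stabilization contact gives a
#' lost patient a re-engagement referral ([refer_patient()]).
#'
#' @param patient Patient record with a crisis this week.
#' @param cfg An `spmi_config`.
#' @param state An `spmi_ecosystem_state`.
#' @return List with `outcome`, updated `patient`, `destination`
#'   environment id (or `NA`), `length_of_stay`, `provider_contact`
#'   (logical), `mh_effect`, costs, and `disposition` for arrests.
#' @export
resolve_crisis <- function(patient, cfg, state) {
  pr <- unlist(cfg$patients$crisis_outcomes)[.crisis_outcomes]
  outcome <- .crisis_outcomes[sample.int(5L, 1L, prob = pr)]
  res <- list(outcome = outcome, patient = patient, destination = NA_character_,
              length_of_stay = NA_integer_, provider_contact = FALSE,
              mh_effect = 0, patient_cost = 0, third_party_cost = 0,
              disposition = NA_character_)

  stabilize <- function(res) {
    csu <- .provider_by_type(cfg, "crisis_stabilization_unit")
    if (state$capacity_left[["crisis_stabilization_unit"]] >= 1) {
      state$capacity_left[["crisis_stabilization_unit"]] <-
        state$capacity_left[["crisis_stabilization_unit"]] - 1
      res$provider_contact <- TRUE
      res$mh_effect <- csu$mh_effect_per_visit
      res$third_party_cost <- csu$third_party_cost
      res$patient_cost <- csu$cost_to_patient_factor *
        cfg$economics$copay_per_factor_visit
      if (isTRUE(res$patient$lost_to_system)) {
        ref <- refer_patient(res$patient, cfg)
        res$patient <- ref$patient
        if (ref$success) {
          res$patient <- .renew_prescription(res$patient, cfg)
        }
      }
    }
    res
  }

  if (outcome == "hospitalization") {
    env <- .env_by_id(cfg, "hospital_inpatient")
    can_admit <- state$capacity_left[["hospital_inpatient"]] >= 1 &&
      (env$capacity < 0 || state$occupancy[["hospital_inpatient"]] < env$capacity)
    if (can_admit) {
      state$capacity_left[["hospital_inpatient"]] <-
        state$capacity_left[["hospital_inpatient"]] - 1
      los <- env$length_of_stay_weeks$min +
        stats::rpois(1, max(0, env$length_of_stay_weeks$mean -
                              env$length_of_stay_weeks$min))
      .move_occupancy(state, as.character(patient$environment), "hospital_inpatient")
      res$patient$previous_environment <- as.character(patient$environment)
      res$patient$environment <- "hospital_inpatient"
      res$patient$environment_weeks_remaining <- los
      res$patient$employed <- FALSE
      res$destination <- "hospital_inpatient"
      res$length_of_stay <- los
    } else {
      res$outcome <- "stabilized"
      res <- stabilize(res)
    }
  } else if (outcome == "arrest") {
    arr <- process_arrest(patient, cfg, state)
    res$patient <- arr$patient
    res$disposition <- arr$disposition
    res$destination <- arr$destination
    res$length_of_stay <- arr$sentence_weeks
    res$provider_contact <- arr$provider_contact
    res$mh_effect <- arr$mh_effect
    res$third_party_cost <- arr$third_party_cost
  } else if (outcome == "homelessness") {
    if (as.character(patient$environment) != "homeless") {
      .move_occupancy(state, as.character(patient$environment), "homeless")
      res$patient$environment <- "homeless"
    }
    res$destination <- "homeless"
  } else if (outcome == "suicide") {
    .move_occupancy(state, as.character(patient$environment), NA)
    res$patient$alive <- FALSE
  } else {
    res <- stabilize(res)
  }
  res
}

.draw_sentence <- function(cfg, degree) {
  s <- cfg$justice$sentence_weeks[[degree]]
  s$min + stats::rpois(1, max(0, s$mean - s$min))
}

#' Process an arrest
#'
#' With probability `cit_officer_probability` a Crisis Intervention Team
#' officer at the scene redirects the patient to the crisis stabilization
#' unit instead of booking. Otherwise the crime degree is drawn; eligible
#' (lowest-degree) offenses enter the Jail Diversion Program with the
#' configured probability -- a supervised treatment overlay with mandatory
#' weekly case-worker contact and no incarceration -- and all other
#' convictions send the patient to the correctional facility with a
#' sentence drawn from the degree's duration distribution. Criminal history
#' escalates on conviction.
#'
#' @param patient Patient record.
#' @param cfg An `spmi_config`.
#' @param state An `spmi_ecosystem_state`.
#' @return List with `disposition` (`cit_redirect`, `diversion`,
#'   `incarcerated`), updated `patient`, `degree`, `sentence_weeks`,
#'   `destination`, `provider_contact`, `mh_effect`, `third_party_cost`.
#' @export
process_arrest <- function(patient, cfg, state) {
  ju <- cfg$justice
  out <- list(disposition = NA_character_, patient = patient,
              degree = NA_character_, sentence_weeks = NA_integer_,
              destination = NA_character_, provider_contact = FALSE,
              mh_effect = 0, third_party_cost = 0)
  if (runif(1) < ju$cit_officer_probability) {
    out$disposition <- "cit_redirect"
    csu <- .provider_by_type(cfg, "crisis_stabilization_unit")
    if (state$capacity_left[["crisis_stabilization_unit"]] >= 1) {
      state$capacity_left[["crisis_stabilization_unit"]] <-
        state$capacity_left[["crisis_stabilization_unit"]] - 1
      out$provider_contact <- TRUE
      out$mh_effect <- csu$mh_effect_per_visit
      out$third_party_cost <- csu$third_party_cost
      if (isTRUE(patient$lost_to_system)) {
        ref <- refer_patient(out$patient, cfg)
        out$patient <- ref$patient
        if (ref$success) {
          out$patient <- .renew_prescription(out$patient, cfg)
        }
      }
    }
    return(out)
  }
  degree <- if (runif(1) < ju$crime_degrees$misdemeanor) "misdemeanor" else "felony"
  out$degree <- degree
  out$patient$criminal_history <- if (degree == "felony") {
    "prior_felony"
  } else if (as.character(patient$criminal_history) == "prior_felony") {
    "prior_felony"
  } else {
    "prior_misdemeanor"
  }
  if (degree == "misdemeanor" && runif(1) < ju$jail_diversion_entry_probability) {
    out$disposition <- "diversion"
    out$patient$in_jail_diversion <- TRUE
    out$patient$diversion_weeks_left <- ju$diversion_weeks
    out$patient$lost_to_system <- FALSE
    out$patient <- .renew_prescription(out$patient, cfg)  # supervised plan
    return(out)
  }
  out$disposition <- "incarcerated"
  out$sentence_weeks <- .draw_sentence(cfg, degree)
  .move_occupancy(state, as.character(patient$environment), "correctional_facility")
  out$patient$environment <- "correctional_facility"
  out$patient$environment_weeks_remaining <- out$sentence_weeks
  out$patient$employed <- FALSE
  out$destination <- "correctional_facility"
  out
}

#' Release a patient whose sentence has ended
#'
#' Draws the discharge location, restores the standard treatment plan (a
#' patient without a medicine is prescribed the default oral one), marks the
#' patient as previously released (the recidivism denominator), and subjects
#' care continuity to a referral handoff: on failure the released patient is
#' lost to the system.
#'
#' @param patient Patient record in the correctional facility with
#'   `environment_weeks_remaining` at 0.
#' @param cfg An `spmi_config`.
#' @param state An `spmi_ecosystem_state` (occupancy update), or `NULL`.
#' @return The updated patient record.
#' @export
release_from_jail <- function(patient, cfg, state = NULL) {
  loc <- unlist(cfg$justice$discharge_location)
  dest <- names(loc)[sample.int(length(loc), 1L, prob = loc)]
  if (!is.null(state)) .move_occupancy(state, "correctional_facility", dest)
  patient$environment <- dest
  patient$environment_weeks_remaining <- NA_integer_
  patient$released_ever <- TRUE
  if (is.null(patient$medicine) || is.na(patient$medicine)) {
    oral <- Filter(function(m) !isTRUE(m$is_long_acting_injectable), cfg$medicines)[[1]]
    patient$medicine <- oral$id
  }
  ref <- refer_patient(patient, cfg)  # on success the receiving provider
  ref$patient                         # holds the discharge plan; else lost
}
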