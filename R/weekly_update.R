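#' One full weekly update of a single patient
#'
#' Applies the fixed weekly decision sequence to one patient against a
#' shared ecosystem state: (1) critical outcomes (crisis, crime, substance
#' abuse, employment; highest priority applies), (2) crisis resolution, (3)
#' the adherence state-chart step, (4) appointment attendance against
#' provider capacity, (5) the medication refill decision, (6) environment
#' length-of-stay countdown and transitions, (7) mental- and
#' physical-health score updates, (8) finances. This is the reference
#' single-patient form of the update; [run_simulation()] applies the same
#' sequence population-wide in compiled code with patients processed in
#' shuffled order each week.
#'
#' @param patient Patient record (a one-row slice of
#'   [synthesize_population()] output as a list; transient fields
#'   `contact_last_week`, `alive`, `previous_environment`, `released_ever`,
#'   `diversion_weeks_left` default sensibly when absent).
#' @param cfg A validated `spmi_config`.
#' @param services An `spmi_ecosystem_state` shared across patients.
#' @param week 1-based week index (drives appointment and refill phases).
#' @return List with the updated `patient` and `events`, a data frame with
#'   columns `kind`, `category`, `patient_cost`, `third_party_cost`.
#' @export
weekly_update <- function(patient, cfg, services, week = services$week) {
  ev <- list()
  emit <- function(kind, category = NA_character_, pc = 0, tc = 0) {
    ev[[length(ev) + 1L]] <<- data.frame(
      kind = kind, category = category, patient_cost = pc,
      third_party_cost = tc, stringsAsFactors = FALSE)
  }
  done <- function(p) {
    events <- if (length(ev)) {
      do.call(rbind, ev)
    } else {
      data.frame(kind = character(), category = character(),
                 patient_cost = numeric(), third_party_cost = numeric(),
                 stringsAsFactors = FALSE)
    }
    list(patient = p, events = events)
  }
  p <- patient
  p$alive <- p$alive %||% TRUE
  p$contact_last_week <- p$contact_last_week %||% FALSE
  p$released_ever <- p$released_ever %||% FALSE
  p$diversion_weeks_left <- p$diversion_weeks_left %||% 0L
  if (!isTRUE(p$alive)) return(done(p))

  dy <- cfg$dynamics
  ec <- cfg$economics
  contact <- FALSE
  provider_eff <- 0
  crisis_shock <- 0
  pat_cost <- 0

  episodic <- !(as.character(p$environment) %in% .envs_stable)
  was_episodic <- episodic

  # (1) critical outcomes -----------------------------------------------------
  outcome <- list(kind = "none")
  if (!episodic) {
    outcome <- draw_critical_outcomes(p, cfg)
    emit(outcome$kind)
    if (outcome$kind == "substance_abuse_start") p$substance_abuse <- TRUE
    if (outcome$kind == "substance_abuse_stop") p$substance_abuse <- FALSE
    if (outcome$kind == "employment_found") p$employed <- TRUE
    if (outcome$kind == "employment_lost") p$employed <- FALSE
    lev_out <- cfg$levers$outreach_probability %||% 0
    if (isTRUE(p$lost_to_system) && lev_out > 0 &&
        !outcome$kind %in% c("crisis", "crime")) {
      env <- .env_by_id(cfg, as.character(p$environment))
      if (runif(1) < lev_out * env$probability_of_being_located) {
        p$lost_to_system <- FALSE
        emit("outreach_reengaged")
      }
    }
  }

  # (2) crisis resolution -----------------------------------------------------
  if (outcome$kind == "crisis") {
    crisis_shock <- dy$crisis_mh_shock
    res <- resolve_crisis(p, cfg, services)
    p <- res$patient
    emit(paste0("crisis_", res$outcome))
    if (!isTRUE(p$alive %||% TRUE)) {
      p$alive <- FALSE
      return(done(p))
    }
    if (isTRUE(res$provider_contact)) {
      contact <- TRUE
      provider_eff <- provider_eff + res$mh_effect
      pat_cost <- pat_cost + res$patient_cost
      emit("csu_contact", "crisis_services", res$patient_cost,
           res$third_party_cost)
    }
  } else if (outcome$kind == "crime") {
    arr <- process_arrest(p, cfg, services)
    p <- arr$patient
    emit(paste0("arrest_", arr$disposition))
    if (isTRUE(arr$provider_contact)) {
      contact <- TRUE
      provider_eff <- provider_eff + arr$mh_effect
      emit("csu_contact", "crisis_services", 0, arr$third_party_cost)
    }
  }
  episodic <- !(as.character(p$environment) %in% .envs_stable)

  # (3) adherence state chart -------------------------------------------------
  noise <- if (dy$stress_noise_sd > 0) rnorm(1, 0, dy$stress_noise_sd) else 0
  stress <- weekly_stress(p, cfg, noise = noise)
  med <- .med_by_id(cfg, p$medicine)
  if (!is.null(med)) {
    was_on <- isTRUE(p$on_medication)
    p <- adherence_step(p, cfg$adherence_chart, list(
      stress = stress,
      recent_provider_contact = p$contact_last_week,
      side_effect_severity = med$short_term_side_effect_severity +
        med$long_term_side_effect_severity,
      cost_to_patient_factor = med$cost_to_patient_factor))
    if (was_on != isTRUE(p$on_medication)) {
      emit(if (was_on) "med_stop" else "med_start")
    }
  }

  # (4) appointments ----------------------------------------------------------
  if (!episodic && !isTRUE(p$lost_to_system)) {
    due <- character()
    if ((week + p$appointment_phase) %% cfg$patients$plan$cmhc_every == 0) {
      due <- c(due, "community_mental_health_center")
    }
    cw_due <- (week + p$appointment_phase) %% cfg$patients$plan$caseworker_every == 0
    if (cw_due || isTRUE(p$in_jail_diversion)) {
      due <- c(due, "case_worker")
    }
    for (ptype in due) {
      att <- attempt_appointment(p, ptype, cfg, services)
      p <- att$patient
      if (att$attended) {
        contact <- TRUE
        provider_eff <- provider_eff + att$mh_effect
        pat_cost <- pat_cost + att$patient_cost
        emit("appt_kept", "outpatient", att$patient_cost, att$third_party_cost)
      } else {
        emit("appt_missed")
      }
    }
  }
  if (!episodic && !isTRUE(p$lost_to_system) &&
      (cfg$patients$plan_transfer_weekly %||% 0) > 0 &&
      runif(1) < cfg$patients$plan_transfer_weekly) {
    # routine plan transfer between providers: a handoff that can fail
    ref <- refer_patient(p, cfg)
    p <- ref$patient
    emit(if (ref$success) "referral_ok" else "referral_fail")
  }
  if (as.character(p$environment) == "hospital_inpatient") {
    contact <- TRUE
    hosp <- .provider_by_type(cfg, "hospital_inpatient")
    if (!is.null(med) && runif(1) < hosp$lai_probability) {
      lai <- Filter(function(m) isTRUE(m$is_long_acting_injectable),
                    cfg$medicines)[[1]]
      p$medicine <- lai$id
      p$lai_weeks_left <- lai$refill_frequency_weeks
    }
  }

  # (5) medication refill -----------------------------------------------------
  med <- .med_by_id(cfg, p$medicine)
  if (!is.null(med)) {
    if (isTRUE(med$is_long_acting_injectable) && p$lai_weeks_left > 0) {
      p$lai_weeks_left <- p$lai_weeks_left - 1
    }
    if (isTRUE(med$is_long_acting_injectable) && isTRUE(p$on_medication) &&
        p$lai_weeks_left <= 0) {
      # depot coverage lapsed without a re-injection
      p$on_medication <- FALSE
      emit("med_stop")
    }
    if (isTRUE(p$on_medication)) {
      if (!isTRUE(med$is_long_acting_injectable) &&
          (week + p$refill_phase) %% med$refill_frequency_weeks == 0) {
        ok <- if (isTRUE(p$lost_to_system)) {
          FALSE
        } else if (episodic) {
          TRUE  # facility-dispensed
        } else {
          runif(1) < access_factor(med$cost_to_patient_factor,
                                   p$financial_resources, cfg$economics)
        }
        if (!ok) {
          p$on_medication <- FALSE
          emit("refill_fail")
          emit("med_stop")
        }
      }
      if (isTRUE(p$on_medication)) {
        copay <- if (episodic) 0 else
          med$cost_to_patient_factor * ec$copay_per_factor_medication
        pat_cost <- pat_cost + copay
        emit("medication_week", "medication", copay, med$system_cost_per_week)
      }
    }
  }

  # (6) environment stay countdown and transition ------------------------------
  if (isTRUE(p$in_jail_diversion)) {
    p$diversion_weeks_left <- max(0L, p$diversion_weeks_left - 1L)
    if (p$diversion_weeks_left == 0L) p$in_jail_diversion <- FALSE
  }
  env_id <- as.character(p$environment)
  if (env_id %in% c("hospital_inpatient", "correctional_facility")) {
    # the admission week does not count against the stay
    if (was_episodic) {
      p$environment_weeks_remaining <- p$environment_weeks_remaining - 1L
    }
    if (was_episodic && p$environment_weeks_remaining <= 0L) {
      if (env_id == "hospital_inpatient") {
        dest <- p$previous_environment %||% "private_residence"
        .move_occupancy(services, "hospital_inpatient", dest)
        p$environment <- dest
        p$environment_weeks_remaining <- NA_integer_
        if (is.null(p$medicine) || is.na(p$medicine)) {
          oral <- Filter(function(m) !isTRUE(m$is_long_acting_injectable),
                         cfg$medicines)[[1]]
          p$medicine <- oral$id
        }
        if (!isTRUE(p$on_medication)) {
          p$on_medication <- TRUE  # discharged with an active prescription
          emit("med_start")
        }
        p <- .renew_prescription(p, cfg)
        ref <- refer_patient(p, cfg)
        p <- ref$patient
        emit(if (ref$success) "referral_ok" else "referral_fail")
      } else {
        p <- release_from_jail(p, cfg, services)
        emit("release")
        emit(if (isTRUE(p$lost_to_system)) "referral_fail" else "referral_ok")
      }
    }
  } else {
    dest <- transition_environment(p, cfg, services$occupancy)
    if (dest != env_id) {
      .move_occupancy(services, env_id, dest)
      if (dest == "homeless") emit("homeless_entry")
      p$environment <- dest
    }
  }

  # (7) score updates ----------------------------------------------------------
  env <- .env_by_id(cfg, as.character(p$environment))
  mh_new <- update_mental_health(p, cfg, list(
    provider_contact = contact, provider_mh_effect = provider_eff,
    environment_mh_effect = env$weekly_mh_effect, stress = stress,
    crisis_shock = crisis_shock))
  p$physical_health <- update_physical_health(p, cfg, list(
    environment_ph_effect = env$weekly_ph_effect))
  p$mental_health <- mh_new

  # (8) finances ---------------------------------------------------------------
  pat_cost <- pat_cost + env$weekly_cost_patient
  emit("environment_week",
       switch(as.character(p$environment),
              hospital_inpatient = "hospitalization",
              correctional_facility = "incarceration",
              "housing"),
       env$weekly_cost_patient, env$weekly_cost_third_party)
  p$financial_resources <- update_finances(p, cfg,
                                           list(patient_costs = pat_cost))
  p$contact_last_week <- contact
  done(p)
}
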