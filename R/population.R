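#' Map a 1-100 mental-health score to its GAF-style band
#'
#' The mental-health score approximates the Global Assessment of Functioning
#' scale, which is defined on 1-100 in ten decile ranges. `mh_category`
#' returns the decile band (1 = scores 1-10, ..., 10 = scores 91-100), or a
#' coarse clinical label used for reporting and for category-conditioned
#' rates: `severe` (1-30), `serious` (31-50), `moderate` (51-70),
#' `mild` (71-100).
#'
#' @param score Numeric vector of scores in `[1, 100]`.
#' @param coarse If `TRUE`, return the coarse four-level label as an ordered
#'   factor; otherwise the decile band index 1-10.
#' @return Integer band indices, or an ordered factor of coarse labels.
#' @export
mh_category <- function(score, coarse = FALSE) {
  if (any(!is.finite(score)) || any(score < 1) || any(score > 100)) {
    stop("mental-health score must lie in [1, 100]", call. = FALSE)
  }
  band <- pmin(10L, (as.integer(ceiling(score)) - 1L) %/% 10L + 1L)
  if (!coarse) return(band)
  lab <- .mh_categories[c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L)][band]
  factor(lab, levels = .mh_categories, ordered = TRUE)
}

# coarse category index 1..4 (severe..mild) for internal numeric use
.mh_cat_idx <- function(score) {
  band <- pmin(10L, (as.integer(ceiling(score)) - 1L) %/% 10L + 1L)
  c(1L, 1L, 1L, 2L, 2L, 3L, 3L, 4L, 4L, 4L)[band]
}

.draw_dist <- function(spec, n, lower = -Inf, upper = Inf) {
  x <- switch(spec$dist,
    normal = rnorm(n, spec$mean, spec$sd),
    beta = rbeta(n, spec$shape1, spec$shape2),
    lognormal = rlnorm(n, spec$meanlog, spec$sdlog),
    point = rep(spec$value, n),
    stop("unknown distribution kind: ", spec$dist, call. = FALSE)
  )
  pmin(upper, pmax(lower, x))
}

.draw_cat <- function(dist, n, levels = NULL) {
  p <- unlist(dist)
  if (length(p) == 0L || sum(p) <= 0) {
    stop("empty categorical distribution", call. = FALSE)
  }
  nm <- names(p)
  idx <- sample.int(length(p), n, replace = TRUE, prob = p)
  if (is.null(levels)) factor(nm[idx], levels = nm) else factor(nm[idx], levels = levels)
}

#' Synthesize the initial patient population
#'
#' Creates `population_size` patient agents by sampling every initial
#' characteristic from the distributions in the profile's patient group.
#' Fields are sampled independently except that the per-patient mental-health
#' floor is clipped to lie at or below the initial mental-health score, and
#' the initial treatment plan (medicine and appointment schedule) is assigned
#' from the plan block. All patients start engaged with the system
#' (`lost_to_system = FALSE`).
#'
#' @param cfg A validated `spmi_config`.
#' @param seed Optional integer seed; if `NULL`, the current RNG state is
#'   used. Given `(cfg, seed)` the population is fully deterministic.
#' @return A data frame with one row per patient.
#' @export
synthesize_population <- function(cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  pa <- cfg$patients
  n <- as.integer(pa$population_size)
  meds <- cfg$medicines
  lai_idx <- which(vapply(meds, function(m) isTRUE(m$is_long_acting_injectable), NA))[1]
  oral_idx <- which(!vapply(meds, function(m) isTRUE(m$is_long_acting_injectable), NA))[1]

  if (n == 0L) {
    return(.empty_population())
  }

  mh <- round(.draw_dist(pa$initial_mental_health, n, 1, 100))
  mh_floor <- pmin(round(.draw_dist(pa$mh_floor, n, 1, 100)), mh)
  ph <- round(.draw_dist(pa$initial_physical_health, n, 1, 100))

  has_med <- runif(n) >= pa$plan$p_no_medicine
  is_lai <- has_med & (runif(n) < pa$plan$p_lai)
  med <- ifelse(!has_med, NA_integer_, ifelse(is_lai, lai_idx, oral_idx))

  env <- .draw_cat(pa$initial_environment, n, levels = .envs_all)

  data.frame(
    id = seq_len(n),
    age_band = .draw_cat(pa$age_bands, n),
    diagnosis = .draw_cat(pa$diagnoses, n),
    mental_health = as.numeric(mh),
    mh_floor = as.numeric(mh_floor),
    physical_health = as.numeric(ph),
    ph_decline_factor = .draw_dist(pa$ph_decline_factor, n),
    stress_base = .draw_dist(pa$stress_base, n, 0, 1),
    family_support = .draw_dist(pa$family_support, n, 0, 1),
    substance_abuse = runif(n) < pa$substance_abuse_initial,
    employed = runif(n) < pa$employed_initial,
    on_medication = has_med & (runif(n) < pa$initial_on_medication),
    medicine = vapply(med, function(i) if (is.na(i)) NA_character_ else meds[[i]]$id, ""),
    lai_weeks_left = ifelse(!is.na(med) & med == lai_idx,
                            meds[[lai_idx]]$refill_frequency_weeks, 0),
    environment = env,
    environment_weeks_remaining = NA_integer_,
    financial_resources = .draw_dist(pa$initial_financial_resources, n, 0, Inf),
    criminal_history = .draw_cat(cfg$justice$initial_criminal_history, n,
                                 levels = c("none", "prior_misdemeanor", "prior_felony")),
    in_jail_diversion = FALSE,
    lost_to_system = FALSE,
    appointment_phase = sample.int(
      as.integer(pa$plan$cmhc_every * pa$plan$caseworker_every), n,
      replace = TRUE) - 1L,
    refill_phase = sample.int(8L, n, replace = TRUE) - 1L,
    stringsAsFactors = FALSE
  )
}

.empty_population <- function() {
  data.frame(
    id = integer(), age_band = factor(), diagnosis = factor(),
    mental_health = numeric(), mh_floor = numeric(), physical_health = numeric(),
    ph_decline_factor = numeric(), stress_base = numeric(),
    family_support = numeric(), substance_abuse = logical(),
    employed = logical(), on_medication = logical(), medicine = character(),
    lai_weeks_left = numeric(), environment = factor(levels = .envs_all),
    environment_weeks_remaining = integer(), financial_resources = numeric(),
    criminal_history = factor(levels = c("none", "prior_misdemeanor", "prior_felony")),
    in_jail_diversion = logical(), lost_to_system = logical(),
    appointment_phase = integer(), refill_phase = integer(),
    stringsAsFactors = FALSE
  )
}

#' Write or read a synthesized population as a flat CSV table
#'
#' @param pop A population data frame from [synthesize_population()].
#' @param path CSV file path.
#' @return `write_population` returns `path` invisibly; `read_population`
#'   returns the population data frame.
#' @export
write_population <- function(pop, path) {
  write.csv(pop, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_population
#' @export
read_population <- function(path) {
  pop <- read.csv(path, stringsAsFactors = FALSE)
  pop$environment <- factor(pop$environment, levels = .envs_all)
  pop$criminal_history <- factor(
    pop$criminal_history, levels = c("none", "prior_misdemeanor", "prior_felony"))
  pop
}
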