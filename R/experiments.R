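# The two care-coordination intervention experiments: parameter
# sweeps over the referral handoff-success lever and the appointment
# compliance lever, with the output measures reported for each.

.lever_paths <- c(
  handoff_success_rate = "levers.handoff_success_rate",
  patient_appointment_compliance_rate = "levers.patient_appointment_compliance_rate")

#' Specify a care-coordination lever sweep
#'
#' The two experiments shift one lever in 1-percentage-point steps around
#' its calibrated baseline: the handoff sweep spans -15 to +20 points, the
#' compliance sweep -10 to +20 points. Shifted rates are clamped to
#' `[0, 1]`. Replications use common random numbers across deltas: the i-th
#' replicate of every delta runs under the same seed, so contrasts against
#' the delta = 0 baseline are paired.
#'
#' @param lever `"handoff_success_rate"` or
#'   `"patient_appointment_compliance_rate"` (unambiguous prefixes
#'   `"handoff"` / `"compliance"` are accepted).
#' @param cfg Base profile (default: the shipped calibrated profile).
#' @param from,to,by Delta range in percentage points (defaults per lever).
#' @param replications Replications per delta point.
#' @param base_seed First replicate seed.
#' @return A list of class `spmi_sweep_spec`.
#' @export
sweep_spec <- function(lever = c("handoff_success_rate",
                                 "patient_appointment_compliance_rate",
                                 "handoff", "compliance"),
                       cfg = load_default_profile(),
                       from = NULL, to = NULL, by = 1,
                       replications = cfg$system$n_replications,
                       base_seed = cfg$system$seed) {
  lever <- match.arg(lever)
  lever <- switch(lever, handoff = "handoff_success_rate",
                  compliance = "patient_appointment_compliance_rate", lever)
  if (is.null(from)) from <- if (lever == "handoff_success_rate") -15 else -10
  if (is.null(to)) to <- 20
  stopifnot(by > 0, to >= from)
  structure(list(lever = lever, cfg = cfg, from = from, to = to, by = by,
                 replications = replications, base_seed = base_seed),
            class = "spmi_sweep_spec")
}

.run_measures <- function(r) {
  m <- r$metrics
  co <- r$costs
  c(on_medication_share = mean(m$on_medication / m$alive),
    incarceration_cost = sum(co$incarceration_patient +
                               co$incarceration_third_party),
    hospitalization_cost = sum(co$hospitalization_patient +
                                 co$hospitalization_third_party),
    private_residence_mean = mean(m$env_private_residence),
    crisis_count = sum(m$crises),
    attendance_rate = sum(m$appts_kept) / max(1, sum(m$appts_scheduled)),
    lost_share = mean(m$lost_to_system / m$alive),
    total_cost = sum(as.matrix(co[, -1])))
}

#' Run a lever sweep
#'
#' For every delta in the spec's range the lever is shifted by that many
#' percentage points (clamped to `[0, 1]`), `replications` paired-seed runs
#' are executed, and the experiment's output measures are recorded. Percent
#' (and percentage-point) changes are computed against the delta = 0 row of
#' the same sweep and are exactly zero there.
#'
#' @param spec An `spmi_sweep_spec`.
#' @param verbose Print progress.
#' @return An `spmi_sweep_result` with a tidy `results` data frame (delta,
#'   measure, mean, se) and a `changes` data frame of changes vs baseline
#'   (percentage points of population share for the medication measure,
#'   percent otherwise).
#' @export
run_sweep <- function(spec, verbose = FALSE) {
  stopifnot(inherits(spec, "spmi_sweep_spec"))
  cfg <- spec$cfg
  path <- .lever_paths[[spec$lever]]
  base_rate <- config_get(cfg, path)
  deltas <- seq(spec$from, spec$to, by = spec$by)
  if (!0 %in% deltas) deltas <- sort(c(0, deltas))
  rows <- list()
  per_run <- list()
  for (d in deltas) {
    rate <- min(1, max(0, base_rate + d / 100))
    cfg_d <- config_set(cfg, path, rate)
    vals <- sapply(seq_len(spec$replications), function(i) {
      .run_measures(run_simulation(cfg_d, seed = spec$base_seed + i - 1L))
    })
    per_run[[as.character(d)]] <- vals
    rows[[as.character(d)]] <- data.frame(
      delta = d, rate = rate, measure = rownames(vals),
      mean = rowMeans(vals),
      se = apply(vals, 1, sd) / sqrt(ncol(vals)),
      row.names = NULL, stringsAsFactors = FALSE)
    if (verbose) message("delta ", d, " done")
  }
  results <- do.call(rbind, rows)
  base <- rows[["0"]]
  basev <- setNames(base$mean, base$measure)
  changes <- do.call(rbind, lapply(rows, function(r) {
    v <- setNames(r$mean, r$measure)
    data.frame(
      delta = r$delta[1],
      on_medication_pp = 100 * (v["on_medication_share"] -
                                  basev["on_medication_share"]),
      incarceration_cost_pct = 100 * (v["incarceration_cost"] /
                                        basev["incarceration_cost"] - 1),
      hospitalization_cost_pct = 100 * (v["hospitalization_cost"] /
                                          basev["hospitalization_cost"] - 1),
      private_residence_pct = 100 * (v["private_residence_mean"] /
                                       basev["private_residence_mean"] - 1),
      crisis_count_pct = 100 * (v["crisis_count"] / basev["crisis_count"] - 1),
      row.names = NULL, stringsAsFactors = FALSE)
  }))
  structure(list(spec = spec, results = results, changes = changes,
                 baseline = basev),
            class = "spmi_sweep_result")
}

#' @export
print.spmi_sweep_result <- function(x, ...) {
  cat("<spmi_sweep_result>", x$spec$lever, "sweep,",
      length(unique(x$results$delta)), "delta points x",
      x$spec$replications, "replications\n")
  print(x$changes, row.names = FALSE, digits = 3)
  invisible(x)
}

.band_rows <- function(result, band) {
  stopifnot(inherits(result, "spmi_sweep_result"), length(band) == 2)
  ch <- result$changes
  if (band[1] < min(ch$delta) || band[2] > max(ch$delta)) {
    stop("band [", band[1], ", ", band[2], "] outside swept range",
         call. = FALSE)
  }
  ch[ch$delta >= band[1] & ch$delta <= band[2], , drop = FALSE]
}

#' Summarize the handoff experiment over an expert-panel band
#'
#' Over the lever shifts in `band` (default the panel's +5 to +15
#' percentage points), returns the min and max of the three reported
#' measures: change in the share of patients on medication (percentage
#' points of the population), and percent reductions in incarceration and
#' hospitalization cost versus the delta = 0 baseline.
#'
#' @param result An `spmi_sweep_result` from the handoff sweep.
#' @param band `c(low, high)` delta band in percentage points.
#' @return Data frame with `measure`, `min`, `max`.
#' @export
handoff_outcomes <- function(result, band = c(5, 15)) {
  rows <- .band_rows(result, band)
  data.frame(
    measure = c("on_medication_improvement_pp",
                "incarceration_cost_reduction_pct",
                "hospitalization_cost_reduction_pct"),
    min = c(min(rows$on_medication_pp),
            min(-rows$incarceration_cost_pct),
            min(-rows$hospitalization_cost_pct)),
    max = c(max(rows$on_medication_pp),
            max(-rows$incarceration_cost_pct),
            max(-rows$hospitalization_cost_pct)),
    stringsAsFactors = FALSE)
}

#' Summarize the appointment-compliance experiment over a band
#'
#' Over the lever shifts in `band` (default +3 to +12 percentage points),
#' returns the min and max of: percent change in patients living in private
#' residence, and percent reductions in the incarceration and
#' hospitalization costs of crisis.
#'
#' @param result An `spmi_sweep_result` from the compliance sweep.
#' @inheritParams handoff_outcomes
#' @return Data frame with `measure`, `min`, `max`.
#' @export
compliance_outcomes <- function(result, band = c(3, 12)) {
  rows <- .band_rows(result, band)
  data.frame(
    measure = c("private_residence_increase_pct",
                "incarceration_cost_reduction_pct",
                "hospitalization_cost_reduction_pct"),
    min = c(min(rows$private_residence_pct),
            min(-rows$incarceration_cost_pct),
            min(-rows$hospitalization_cost_pct)),
    max = c(max(rows$private_residence_pct),
            max(-rows$incarceration_cost_pct),
            max(-rows$hospitalization_cost_pct)),
    stringsAsFactors = FALSE)
}

#' Write sweep results to a tidy CSV
#'
#' @param result An `spmi_sweep_result`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sweep <- function(result, path) {
  write.csv(result$results, path, row.names = FALSE)
  invisible(path)
}
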