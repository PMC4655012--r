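#' Service-access multiplier from cost-to-patient factor and resources
#'
#' Medicines and provider services carry a cost-to-patient factor on a 0-5
#' scale that lowers the probability of accessing them; personal financial
#' resources soften the barrier. A factor of 0 (free at point of use) always
#' yields 1. The multiplier is monotone non-increasing in the factor and
#' monotone non-decreasing in resources:
#' `1 - (f/5) * (1 - access_floor) * (1 - rho/2)` with
#' `rho = min(1, resources / resources_ref)`, so the configured
#' `access_floor` is attained at factor 5 with zero resources.
#'
#' @param cost_to_patient_factor Integer factor in `{0,...,5}`.
#' @param resources Nonnegative financial resources.
#' @param economics The `economics` block of an `spmi_config` (fields
#'   `resources_ref`, `access_floor`).
#' @return Multiplier in `[0, 1]`.
#' @export
access_factor <- function(cost_to_patient_factor, resources, economics) {
  f <- cost_to_patient_factor
  if (any(!f %in% 0:5)) {
    stop("cost-to-patient factor must be in {0,...,5}", call. = FALSE)
  }
  rho <- pmin(1, pmax(0, resources) / economics$resources_ref)
  1 - (f / 5) * (1 - economics$access_floor) * (1 - rho / 2)
}

#' Create an empty cost ledger
#'
#' The ledger accumulates weekly costs per category (medication, outpatient
#' services, hospitalization, incarceration, housing/shelter, crisis
#' services) split into patient-borne and third-party (insurer, government,
#' private organizations) amounts.
#'
#' @param n_weeks Number of weekly rows.
#' @return An object of class `spmi_ledger`.
#' @export
new_cost_ledger <- function(n_weeks) {
  m <- matrix(0, nrow = n_weeks, ncol = 2L * length(.cost_categories),
              dimnames = list(NULL, paste0(rep(.cost_categories, each = 2L),
                                           c("_patient", "_third_party"))))
  structure(list(weekly = m, posted_ids = character()), class = "spmi_ledger")
}

#' Post a costed event to a ledger
#'
#' Adds the event's patient-borne and third-party amounts to the matching
#' category and week. Posting is idempotent per event id: an event whose
#' `id` has already been posted leaves the ledger unchanged.
#'
#' @param event A list with fields `id` (unique string), `week` (1-based),
#'   `category` (one of the ledger categories), `patient` and `third_party`
#'   (nonnegative amounts).
#' @param ledger An `spmi_ledger`.
#' @return The updated ledger.
#' @export
cost_event <- function(event, ledger) {
  if (!event$category %in% .cost_categories) {
    stop("unknown cost category: ", event$category, call. = FALSE)
  }
  if (event$id %in% ledger$posted_ids) {
    return(ledger)
  }
  stopifnot(event$patient >= 0, event$third_party >= 0,
            event$week >= 1, event$week <= nrow(ledger$weekly))
  ledger$weekly[event$week, paste0(event$category, "_patient")] <-
    ledger$weekly[event$week, paste0(event$category, "_patient")] + event$patient
  ledger$weekly[event$week, paste0(event$category, "_third_party")] <-
    ledger$weekly[event$week, paste0(event$category, "_third_party")] + event$third_party
  ledger$posted_ids <- c(ledger$posted_ids, event$id)
  ledger
}

#' Ledger totals by category and payer
#'
#' @param ledger An `spmi_ledger`.
#' @return A data frame with `category`, `patient`, `third_party`, `total`.
#' @export
ledger_totals <- function(ledger) {
  tot <- colSums(ledger$weekly)
  data.frame(
    category = .cost_categories,
    patient = unname(tot[paste0(.cost_categories, "_patient")]),
    third_party = unname(tot[paste0(.cost_categories, "_third_party")]),
    total = unname(tot[paste0(.cost_categories, "_patient")] +
                     tot[paste0(.cost_categories, "_third_party")]),
    stringsAsFactors = FALSE
  )
}

#' @export
print.spmi_ledger <- function(x, ...) {
  cat("<spmi_ledger>", nrow(x$weekly), "weeks,",
      length(x$posted_ids), "posted events\n")
  print(ledger_totals(x))
  invisible(x)
}

#' Weekly update of a patient's financial resources
#'
#' Resources rise by employment income (or benefit payments when
#' unemployed) and fall by the week's patient-borne costs, floored at zero.
#'
#' @param patient A patient record (list or one-row data frame) with fields
#'   `employed` and `financial_resources`.
#' @param cfg An `spmi_config`.
#' @param events A list with `patient_costs`: total patient-borne costs
#'   accrued this week.
#' @return The updated resources (nonnegative scalar).
#' @export
update_finances <- function(patient, cfg, events = list(patient_costs = 0)) {
  income <- if (isTRUE(patient$employed)) {
    cfg$patients$income_employed_weekly
  } else {
    cfg$patients$benefits_weekly
  }
  max(0, patient$financial_resources + income - (events$patient_costs %||% 0))
}
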