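# Tiered calibration: tune profile parameters so that simulated aggregate
# outputs match reference targets, tier by tier -- first a single headline
# statistic (annual crisis count), then the crisis-outcome mix, then the
# lower-level drivers -- re-checking earlier tiers after later ones, since
# a single-parameter change rarely moves a single metric.

#' Path of the shipped calibration targets file
#' @return File path of the packaged targets file.
#' @export
default_targets_path <- function() {
  system.file("extdata", "calibration_targets.yaml", package = "spmiecosim",
              mustWork = TRUE)
}

#' Load calibration targets
#'
#' The targets file defines tiers, each with reference metrics (name,
#' reference value, relative tolerance) and the profile parameters that may
#' be tuned for that tier (dotted config paths with bounds; the path prefix
#' `scale:` tunes a common multiplier applied to every numeric entry under
#' the path).
#'
#' @param path YAML targets file (default: the shipped file).
#' @return List of class `spmi_calibration_targets`.
#' @export
load_calibration_targets <- function(path = default_targets_path()) {
  raw <- yaml::read_yaml(path)
  stopifnot(!is.null(raw$tiers), length(raw$tiers) >= 1)
  for (t in raw$tiers) {
    stopifnot(!is.null(t$tier), length(t$metrics) >= 1)
    for (m in t$metrics) {
      stopifnot(!is.null(m$metric), is.numeric(m$reference),
                is.numeric(m$tolerance), m$tolerance > 0)
    }
  }
  structure(raw, class = "spmi_calibration_targets")
}

# metric extraction from a pooled replication summary
.calibration_metric <- function(pooled, name) {
  hit <- pooled$metric == name
  if (!any(hit)) stop("unknown calibration metric: ", name, call. = FALSE)
  pooled$mean[hit][1]
}

.apply_tunable <- function(cfg, path, value) {
  if (startsWith(path, "scale:")) {
    real <- sub("^scale:", "", path)
    node <- config_get(cfg, real)
    scaled <- rapply(list(node), function(x) x * value, classes = "numeric",
                     how = "replace")[[1]]
    config_set(cfg, real, scaled)
  } else {
    config_set(cfg, path, value)
  }
}

.tunable_start <- function(path) if (startsWith(path, "scale:")) 1 else NULL

#' Calibrate a profile to tiered reference targets
#'
#' For each tier in ascending order, runs a bounded coordinate-descent
#' search (golden-section line search per parameter) over that tier's
#' tunable parameters. The objective is the maximum relative error over the
#' tier's metrics plus all earlier tiers' metrics (so later tiers cannot
#' silently break earlier ones), evaluated as a replication mean under
#' common random numbers.
#'
#' @param cfg Starting `spmi_config`.
#' @param targets An `spmi_calibration_targets` (default: shipped file).
#' @param n_reps Replications per objective evaluation.
#' @param budget Maximum number of objective evaluations.
#' @param base_seed Seed for the common-random-number replication set.
#' @param verbose Print progress.
#' @return List of class `spmi_calibration_result`: `config` (tuned),
#'   `achieved` (per-target data frame with relative errors and a
#'   `within_tolerance` flag), `evaluations`, `converged`.
#' @export
calibrate <- function(cfg, targets = load_calibration_targets(),
                      n_reps = 4, budget = 60,
                      base_seed = cfg$system$seed, verbose = FALSE) {
  stopifnot(inherits(targets, "spmi_calibration_targets"))
  tiers <- targets$tiers[order(vapply(targets$tiers, function(t) t$tier, 0))]
  evals <- 0L

  metrics_upto <- function(k) do.call(c, lapply(tiers[seq_len(k)], `[[`, "metrics"))

  objective <- function(cfg, k) {
    evals <<- evals + 1L
    pooled <- run_replications(cfg, n = n_reps, base_seed = base_seed)$pooled
    errs <- vapply(metrics_upto(k), function(m) {
      abs(.calibration_metric(pooled, m$metric) - m$reference) / abs(m$reference)
    }, 0)
    max(errs)
  }
  rel_errors <- function(cfg) {
    pooled <- run_replications(cfg, n = n_reps, base_seed = base_seed)$pooled
    do.call(rbind, lapply(seq_along(tiers), function(k) {
      do.call(rbind, lapply(tiers[[k]]$metrics, function(m) {
        sim <- .calibration_metric(pooled, m$metric)
        err <- abs(sim - m$reference) / abs(m$reference)
        data.frame(tier = tiers[[k]]$tier, metric = m$metric,
                   reference = m$reference, simulated = sim,
                   rel_error = err, tolerance = m$tolerance,
                   within_tolerance = err <= m$tolerance,
                   stringsAsFactors = FALSE)
      }))
    }))
  }

  golden <- function(f, lo, hi, tol, max_iter) {
    phi <- (sqrt(5) - 1) / 2
    a <- lo; b <- hi
    x1 <- b - phi * (b - a); x2 <- a + phi * (b - a)
    f1 <- f(x1); f2 <- f(x2)
    it <- 2L
    while (b - a > tol && it < max_iter && evals < budget) {
      if (f1 <= f2) {
        b <- x2; x2 <- x1; f2 <- f1
        x1 <- b - phi * (b - a); f1 <- f(x1)
      } else {
        a <- x1; x1 <- x2; f1 <- f2
        x2 <- a + phi * (b - a); f2 <- f(x2)
      }
      it <- it + 1L
    }
    if (f1 <= f2) list(x = x1, f = f1) else list(x = x2, f = f2)
  }

  current <- cfg
  for (k in seq_along(tiers)) {
    tier <- tiers[[k]]
    tunables <- tier$tunable
    if (is.null(tunables) || length(tunables) == 0L) {
      stop("tier ", tier$tier, " has no tunable parameters", call. = FALSE)
    }
    best <- objective(current, k)
    tol_k <- min(vapply(metrics_upto(k), function(m) m$tolerance, 0))
    if (best <= tol_k) {
      if (verbose) message("tier ", tier$tier, ": already within tolerance")
      next
    }
    for (tn in tunables) {
      if (evals >= budget || best <= tol_k) break
      f <- function(x) objective(.apply_tunable(current, tn$path, x), k)
      span <- tn$upper - tn$lower
      opt <- golden(f, tn$lower, tn$upper, tol = span / 64,
                    max_iter = 12L)
      if (opt$f < best) {
        current <- .apply_tunable(current, tn$path, opt$x)
        best <- opt$f
        if (verbose) {
          message("tier ", tier$tier, ": ", tn$path, " -> ",
                  signif(opt$x, 4), " (objective ", signif(best, 3), ")")
        }
      }
    }
  }

  achieved <- rel_errors(current)
  v <- validate_config(current)
  if (nrow(v) > 0L) {
    stop("calibration produced an invalid profile: ", v$field[1], call. = FALSE)
  }
  structure(list(config = current, achieved = achieved,
                 evaluations = evals,
                 converged = all(achieved$within_tolerance)),
            class = "spmi_calibration_result")
}

#' @export
print.spmi_calibration_result <- function(x, ...) {
  cat("<spmi_calibration_result>", x$evaluations, "evaluations,",
      if (x$converged) "converged" else "NOT converged", "\n")
  print(x$achieved, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Check the internal variability of mental-health trajectories
#'
#' Computes, for each patient class (coarse category of the initial
#' mental-health score), the standard deviation over weeks of the class
#' mean mental-health score, and flags classes whose temporal variability
#' exceeds the supplied bound. Under frozen dynamics (all rates and deltas
#' zero) every class variability is exactly zero.
#'
#' @param result An `spmi_run_result`.
#' @param bounds Single bound or named per-class vector
#'   (`severe`, `serious`, `moderate`, `mild`).
#' @return Data frame with `class`, `variability`, `bound`, `flagged`.
#' @export
variability_check <- function(result, bounds = 5) {
  m <- result$metrics
  cls <- .mh_categories
  if (length(bounds) == 1L && is.null(names(bounds))) {
    bounds <- setNames(rep(bounds, 4L), cls)
  }
  out <- do.call(rbind, lapply(cls, function(cc) {
    series <- m[[paste0("class_mh_", cc)]]
    v <- if (length(series) > 1L && any(!is.na(series))) {
      sd(series[!is.na(series)])
    } else NA_real_
    data.frame(class = cc, variability = v, bound = bounds[[cc]],
               flagged = !is.na(v) && v > bounds[[cc]],
               stringsAsFactors = FALSE)
  }))
  out
}
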