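#' Protocol and threshold configuration
#'
#' Builds the run configuration used throughout the package: protocol
#' constants (draw schedule, dose entry), calibrator and QC level
#' definitions, and acceptance thresholds. Every threshold has the
#' field-standard default; all are overridable, and a JSON config file can
#' supply overrides via [load_config()].
#'
#' @param calibrator_levels Nominal calibrator concentrations (ug/mL).
#' @param qc_levels Nominal quality-control concentrations (ug/mL).
#' @param nominal_times Protocol draw times after injection (min).
#' @param n_draws Number of timed draws required per test order.
#' @param formulation_concentration Iohexol formulation strength (mg/mL)
#'   used when dose is entered as an injected volume.
#' @param default_volume Default injected volume (mL).
#' @param loq Lower limit of quantification used for below-range flagging
#'   (ug/mL).
#' @param calibrator_recovery_limits Acceptable per-calibrator back-fit
#'   recovery window (percent of nominal).
#' @param qc_recovery_limits Acceptable QC recovery window (percent).
#' @param cv_limit Maximum acceptable coefficient of variation (percent).
#' @param carryover_limit Maximum acceptable carryover (percent, strict).
#' @param stability_limits Acceptable stability recovery window (percent).
#' @param r2_threshold Minimum clearance-curve R-squared below which a
#'   result is withheld for review.
#' @param min_draw_time Earliest draw time (min) considered free of
#'   distribution-phase contamination; earlier draws are flagged.
#' @param bsa_range Plausible body-surface-area range (m^2); values outside
#'   are flagged.
#' @param weighting Calibration weighting scheme, `"inverse_concentration"`
#'   (1/x) or `"none"`.
#' @param reject_bad_calibration If `TRUE`, a calibration curve with any
#'   back-fit recovery outside `calibrator_recovery_limits` is a hard
#'   failure; if `FALSE` it is flagged but usable.
#'
#' @return A list of class `"gfr_config"`.
#' @export
#' @examples
#' cfg <- gfr_config()
#' cfg$calibrator_levels
gfr_config <- function(calibrator_levels = c(5, 10, 50, 250, 750, 1000),
                       qc_levels = c(20, 150, 800),
                       nominal_times = c(120, 180, 240),
                       n_draws = 3,
                       formulation_concentration = 647.1,
                       default_volume = 5,
                       loq = 3.3,
                       calibrator_recovery_limits = c(85, 115),
                       qc_recovery_limits = c(85, 115),
                       cv_limit = 15,
                       carryover_limit = 1,
                       stability_limits = c(85, 115),
                       r2_threshold = 0.98,
                       min_draw_time = 120,
                       bsa_range = c(0.2, 3.5),
                       weighting = c("inverse_concentration", "none"),
                       reject_bad_calibration = FALSE) {
  weighting <- match.arg(weighting)
  stopifnot(length(calibrator_levels) >= 2, all(calibrator_levels > 0),
            all(qc_levels > 0), n_draws >= 2,
            formulation_concentration > 0, loq >= 0,
            r2_threshold > 0, r2_threshold <= 1,
            cv_limit > 0, cv_limit <= 100,
            carryover_limit > 0, carryover_limit <= 100)
  structure(list(
    calibrator_levels = sort(calibrator_levels),
    qc_levels = sort(qc_levels),
    nominal_times = nominal_times,
    n_draws = n_draws,
    formulation_concentration = formulation_concentration,
    default_volume = default_volume,
    loq = loq,
    calibrator_recovery_limits = calibrator_recovery_limits,
    qc_recovery_limits = qc_recovery_limits,
    cv_limit = cv_limit,
    carryover_limit = carryover_limit,
    stability_limits = stability_limits,
    r2_threshold = r2_threshold,
    min_draw_time = min_draw_time,
    bsa_range = bsa_range,
    weighting = weighting,
    reject_bad_calibration = reject_bad_calibration
  ), class = "gfr_config")
}

#' Load configuration overrides from a JSON file
#'
#' Reads a JSON object whose keys match [gfr_config()] arguments and merges
#' them over the defaults. Unknown keys are an error so typos are caught.
#'
#' @param path Path to a JSON configuration file.
#' @return A `"gfr_config"` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  overrides <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(gfr_config))
  bad <- setdiff(names(overrides), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  do.call(gfr_config, overrides)
}

#' @export
print.gfr_config <- function(x, ...) {
  cat("iohexol mGFR run configuration\n")
  cat("  calibrators (ug/mL): ", paste(x$calibrator_levels, collapse = ", "), "\n")
  cat("  QCs (ug/mL):         ", paste(x$qc_levels, collapse = ", "), "\n")
  cat("  draw schedule (min): ", paste(x$nominal_times, collapse = ", "),
      " (", x$n_draws, " draws)\n", sep = "")
  cat("  formulation:         ", x$formulation_concentration, "mg/mL\n")
  cat("  LOQ flag threshold:  ", x$loq, "ug/mL\n")
  cat("  R2 withhold below:   ", x$r2_threshold, "\n")
  invisible(x)
}

# Run a block with a locally-seeded RNG, restoring the caller's RNG state.
# seed = NULL leaves the current RNG stream untouched.
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed))
    stop("seed must be a single number")
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
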