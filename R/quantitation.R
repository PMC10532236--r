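#' Fit the calibration line from calibrator specimens
#'
#' Regresses the analyte/internal-standard area ratio on the nominal
#' calibrator concentration by (optionally weighted) least squares. The
#' default weighting is 1/x (inverse concentration): the calibrated range
#' spans 200-fold, and unweighted fits let the top calibrator dominate
#' low-end accuracy. Back-fit recoveries (back-calculated / nominal x 100)
#' are computed per level, averaging duplicate rows at the same level; a
#' curve with any recovery outside the acceptance window is flagged
#' rejected (a hard failure when `config$reject_bad_calibration` is TRUE).
#' Blanks are never part of the fit and the line is not forced through
#' zero.
#'
#' @param calibrators Data frame with columns `nominal_concentration` and
#'   either `area_ratio` or both `analyte_area` and `istd_area`.
#' @param weighting `"inverse_concentration"` (default) or `"none"`.
#' @param config A [gfr_config()] supplying the recovery acceptance window.
#'
#' @return An object of class `"calibration_model"`: slope, intercept,
#'   `r_squared` (coefficient of determination of the weighted fit),
#'   `recoveries` (per-level back-fit recovery, percent), `accepted`,
#'   `calibration_range`, and the fitted `lm` object.
#' @export
#' @examples
#' cal <- data.frame(nominal_concentration = c(5, 10, 50, 250, 750, 1000))
#' cal$area_ratio <- 0.01 * cal$nominal_concentration
#' fit_calibration(cal)
fit_calibration <- function(calibrators,
                            weighting = NULL,
                            config = gfr_config()) {
  if (is.null(weighting)) weighting <- config$weighting
  weighting <- match.arg(weighting, c("inverse_concentration", "none"))
  calibrators <- as.data.frame(calibrators)
  if (!"area_ratio" %in% names(calibrators)) {
    if (!all(c("analyte_area", "istd_area") %in% names(calibrators)))
      stop("calibrators need area_ratio or analyte_area + istd_area columns")
    if (any(calibrators$istd_area <= 0))
      stop("istd_area must be > 0 for all calibrators")
    calibrators$area_ratio <- calibrators$analyte_area / calibrators$istd_area
  }
  conc <- calibrators$nominal_concentration
  if (any(is.na(conc)) || any(conc <= 0))
    stop("all calibrators need a positive nominal_concentration")
  if (length(unique(conc)) < 2)
    stop("insufficient calibration: need >= 2 distinct calibrator levels")

  w <- if (weighting == "inverse_concentration") 1 / conc else rep(1, length(conc))
  fit <- stats::lm(area_ratio ~ nominal_concentration,
                   data = calibrators, weights = w)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (!is.finite(slope) || slope <= 0)
    stop("calibration slope must be positive; got ", format(slope))
  r2 <- suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly

  # back-fit recovery per level, duplicates averaged before reporting
  back <- (calibrators$area_ratio - intercept) / slope
  lev <- sort(unique(conc))
  rec <- vapply(lev, function(l) mean(back[conc == l]) / l * 100, numeric(1))
  names(rec) <- format(lev, trim = TRUE)
  lims <- config$calibrator_recovery_limits
  ok <- rec >= lims[1] & rec <= lims[2]
  accepted <- all(ok)
  if (!accepted && isTRUE(config$reject_bad_calibration))
    stop("calibration rejected: back-fit recovery outside ",
         lims[1], "-", lims[2], "% at level(s) ",
         paste(names(rec)[!ok], collapse = ", "))

  structure(list(slope = slope, intercept = intercept,
                 weighting_scheme = weighting,
                 r_squared = r2, recoveries = rec,
                 recovery_ok = ok, accepted = accepted,
                 calibration_range = range(conc), fit = fit),
            class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf("Calibration: ratio = %.6g * conc %+.6g (%s weighting)\n",
              x$slope, x$intercept, x$weighting_scheme))
  cat(sprintf("  R^2 = %.5f, range %.4g-%.4g ug/mL, %s\n",
              x$r_squared, x$calibration_range[1], x$calibration_range[2],
              if (x$accepted) "accepted" else "REJECTED"))
  cat("  back-fit recovery (%):",
      paste(sprintf("%s: %.1f", names(x$recoveries), x$recoveries),
            collapse = ", "), "\n")
  invisible(x)
}

#' Back-calculate a concentration from an area ratio
#'
#' Inverts the calibration line: concentration = (ratio - intercept) /
#' slope. Results are never truncated; instead a range flag is attached:
#' `"below_loq"` when below the configured lower limit of quantification,
#' `"above_range"` when above the top calibrator (re-dilution advised),
#' `"ok"` otherwise.
#'
#' @param area_ratio Analyte/internal-standard area ratio (vectorized).
#' @param model A `"calibration_model"`.
#' @param loq Lower limit of quantification (ug/mL).
#' @param config A [gfr_config()] (supplies `loq` when not given).
#'
#' @return Data frame with `concentration` (ug/mL) and `flag`.
#' @export
back_calculate <- function(area_ratio, model, loq = NULL,
                           config = gfr_config()) {
  if (!inherits(model, "calibration_model") || model$slope <= 0)
    stop("invalid calibration model")
  if (is.null(loq)) loq <- config$loq
  conc <- (area_ratio - model$intercept) / model$slope
  flag <- rep("ok", length(conc))
  flag[conc < loq] <- "below_loq"
  flag[conc > model$calibration_range[2]] <- "above_range"
  data.frame(concentration = conc, flag = flag, stringsAsFactors = FALSE)
}

#' Evaluate quality-control specimens against their nominal values
#'
#' Per QC level, computes the mean back-calculated recovery (percent of
#' nominal) and, when the level is replicated, the coefficient of
#' variation. A level passes when its recovery lies in the acceptance
#' window and (if replicated) the CV does not exceed the CV limit. The
#' batch is accepted only when every configured level is present and
#' passes; a missing level is an error.
#'
#' @param qcs Data frame with `nominal_concentration` and either
#'   `area_ratio` or `analyte_area` + `istd_area`.
#' @param model A `"calibration_model"`.
#' @param config A [gfr_config()].
#'
#' @return A list with `levels` (data frame: nominal, n, mean
#'   concentration, recovery percent, cv percent, pass) and `batch_ok`.
#' @export
#' @examples
#' cal <- data.frame(nominal_concentration = c(5, 10, 50, 250, 750, 1000))
#' cal$area_ratio <- 0.01 * cal$nominal_concentration
#' m <- fit_calibration(cal)
#' qc <- data.frame(nominal_concentration = c(20, 150, 800),
#'                  area_ratio = 0.01 * c(20, 150, 800))
#' evaluate_qc(qc, m)$batch_ok
evaluate_qc <- function(qcs, model, config = gfr_config()) {
  qcs <- as.data.frame(qcs)
  if (!"area_ratio" %in% names(qcs))
    qcs$area_ratio <- qcs$analyte_area / qcs$istd_area
  missing_lev <- setdiff(config$qc_levels, qcs$nominal_concentration)
  if (length(missing_lev))
    stop("batch invalid: missing QC level(s) ",
         paste(missing_lev, collapse = ", "), " ug/mL")
  bc <- back_calculate(qcs$area_ratio, model, config = config)
  lims <- config$qc_recovery_limits
  out <- lapply(sort(unique(qcs$nominal_concentration)), function(l) {
    v <- bc$concentration[qcs$nominal_concentration == l]
    m <- mean(v)
    cv <- if (length(v) > 1) stats::sd(v) / m * 100 else NA_real_
    rec <- m / l * 100
    pass <- rec >= lims[1] && rec <= lims[2] &&
      (is.na(cv) || cv <= config$cv_limit)
    data.frame(nominal = l, n = length(v), mean_concentration = m,
               recovery = rec, cv = cv, pass = pass)
  })
  levels <- do.call(rbind, out)
  list(levels = levels, batch_ok = all(levels$pass))
}

#' Quantitate an instrument batch
#'
#' End-to-end per-batch quantitation: fits the calibration from the batch's
#' calibrator rows, evaluates its QC rows, and back-calculates a
#' concentration (with range flag) for every specimen. This is the
#' quantitation report consumed by the clearance calculation.
#'
#' @param batch An instrument batch as returned by
#'   [parse_instrument_csv()] or [simulate_instrument_batch()] (the
#'   `$batch`/`$samples` data frame or the list itself).
#' @param config A [gfr_config()].
#'
#' @return A list with `report` (data frame: barcode, role, concentration,
#'   flag), `calibration` (the fitted model), `qc` (the QC evaluation),
#'   and `batch_ok`.
#' @export
quantitate_batch <- function(batch, config = gfr_config()) {
  tab <- if (is.data.frame(batch)) batch
         else if (!is.null(batch$samples)) batch$samples
         else batch$batch
  stopifnot(is.data.frame(tab))
  tab$area_ratio <- tab$analyte_area / tab$istd_area
  model <- fit_calibration(tab[tab$role == "calibrator", , drop = FALSE],
                           config = config)
  qc <- evaluate_qc(tab[tab$role == "qc", , drop = FALSE], model,
                    config = config)
  bc <- back_calculate(tab$area_ratio, model, config = config)
  report <- data.frame(barcode = tab$barcode, role = tab$role,
                       concentration = bc$concentration, flag = bc$flag,
                       stringsAsFactors = FALSE)
  list(report = report, calibration = model, qc = qc,
       batch_ok = model$accepted && qc$batch_ok)
}
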