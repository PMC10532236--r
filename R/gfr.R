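#' Fit the slow (renal elimination) compartment
#'
#' Ordinary least squares of the natural log of concentration on elapsed
#' time. For draws taken at or after 120 min the distribution phase has
#' essentially decayed and the points lie on the terminal monoexponential;
#' earlier draws are flagged as potentially contaminated by the fast
#' phase. The log base is immaterial for the clearance (slope and
#' intercept rescale together); natural log is used throughout.
#'
#' @param t Elapsed times since injection (min), length >= 2.
#' @param conc Concentrations (ug/mL), all > 0.
#' @param min_time Earliest draw time regarded as distribution-free;
#'   earlier draws add an `"early_draw"` flag.
#'
#' @return A list with `log_intercept` (ln mg/L at t = 0), `slope`
#'   (1/min, negative), `beta` (= -slope), `r_squared`, and `flags`.
#' @export
#' @examples
#' fit_slow_compartment(c(120, 180, 240), c(200, 100, 50))
fit_slow_compartment <- function(t, conc, min_time = 120) {
  if (length(t) != length(conc)) stop("t and conc lengths differ")
  if (length(t) < 2) stop("need at least 2 timed concentrations")
  if (any(!is.finite(conc)) || any(conc <= 0))
    stop("all concentrations must be finite and > 0")
  if (is.unsorted(t, strictly = TRUE)) stop("times must be strictly increasing")
  flags <- character(0)
  if (any(t < min_time)) flags <- c(flags, "early_draw")

  fit <- stats::lm(log(conc) ~ t)
  slope <- unname(stats::coef(fit)[2])
  intercept <- unname(stats::coef(fit)[1])
  if (slope >= 0)
    stop("non-decaying curve: concentrations do not fall with time")
  r2 <- if (length(t) == 2) 1 else
    suppressWarnings(summary(fit)$r.squared)  # exact fits warn harmlessly
  list(log_intercept = intercept, slope = slope, beta = -slope,
       r_squared = r2, flags = flags)
}

#' Slope-intercept plasma clearance (C2)
#'
#' Clearance from the extrapolated terminal phase only: the zero-time
#' intercept C0' = exp(log_intercept) (mg/L) and decay constant
#' beta = -slope give AUC = C0'/beta (mg min/L) for the monoexponential
#' extrapolated over all time, and C2 = dose / AUC. Because the fast
#' distribution phase is ignored, this AUC underestimates the true AUC and
#' C2 overestimates the GFR; [bm_correct()] compensates.
#'
#' @param log_intercept Natural-log intercept at t = 0 (ln mg/L).
#' @param slope Terminal slope (1/min), must be negative.
#' @param dose Administered dose (mg).
#'
#' @return A list with `c0` (mg/L), `beta` (1/min), `auc_slow`
#'   (mg min/L), and `c2` (mL/min).
#' @export
#' @examples
#' f <- fit_slow_compartment(c(120, 180, 240), c(200, 100, 50))
#' slope_intercept_clearance(f$log_intercept, f$slope, dose = 3235.5)$c2
slope_intercept_clearance <- function(log_intercept, slope, dose) {
  if (!is.finite(slope) || slope >= 0) stop("slope must be negative")
  if (!is.finite(dose) || dose <= 0) stop("dose must be > 0")
  c0 <- exp(log_intercept)          # mg/L
  beta <- -slope                    # 1/min
  auc <- c0 / beta                  # mg*min/L
  c2 <- dose / auc * 1000           # L/min -> mL/min (the one unit conversion)
  list(c0 = c0, beta = beta, auc_slow = auc, c2 = c2)
}

#' Brochner-Mortensen correction
#'
#' Corrects the slope-intercept clearance for the unmeasured fast
#' distribution phase with the quadratic
#' GFR = 0.990778 C2 - 0.001218 C2^2 (C2 and GFR in mL/min). The
#' correction always reduces the estimate for positive C2 and is strictly
#' increasing up to about 407 mL/min, far beyond the physiologic range; a
#' `"c2_out_of_range"` warning attribute is attached above 400 mL/min,
#' where the parabola approaches its turnover and the correction was never
#' derived.
#'
#' @param c2 Uncorrected slope-intercept clearance (mL/min), >= 0.
#' @return Corrected GFR (mL/min), with attribute `flags` when c2 > 400.
#' @export
#' @examples
#' bm_correct(100)  # 86.8978
bm_correct <- function(c2) {
  if (any(!is.finite(c2)) || any(c2 < 0)) stop("c2 must be >= 0")
  out <- 0.990778 * c2 - 0.001218 * c2^2
  if (any(c2 > 400))
    attr(out, "flags") <- "c2_out_of_range"
  out
}

#' Normalize a GFR to the 1.73 m^2 reference body surface area
#'
#' @param gfr GFR (mL/min).
#' @param bsa Body surface area (m^2), > 0.
#' @return GFR in mL/min/1.73 m^2.
#' @export
normalize_bsa <- function(gfr, bsa) {
  if (any(!is.finite(bsa)) || any(bsa <= 0)) stop("bsa must be > 0")
  gfr * 1.73 / bsa
}

#' Classify a normalized GFR against the KDIGO donor cutoffs
#'
#' Living-donor evaluation categories: below 60 mL/min/1.73 m^2 excludes
#' donation, 90 or above is acceptable, and 60-89 is evaluated together
#' with the candidate's long-term risk profile.
#'
#' @param gfr_normalized GFR in mL/min/1.73 m^2, >= 0. Vectorized.
#' @return Character vector: `"exclusion"`, `"intermediate"`, or
#'   `"acceptance"`.
#' @export
#' @examples
#' classify_kdigo(c(59.9, 75, 90))
classify_kdigo <- function(gfr_normalized) {
  if (any(!is.finite(gfr_normalized)) || any(gfr_normalized < 0))
    stop("gfr_normalized must be >= 0")
  ifelse(gfr_normalized < 60, "exclusion",
         ifelse(gfr_normalized < 90, "intermediate", "acceptance"))
}

#' Compute a measured GFR for one test order
#'
#' The end-to-end per-patient calculation: elapsed minutes from the
#' recorded injection and draw timestamps (never the nominal schedule),
#' log-linear fit of the terminal phase, slope-intercept clearance,
#' Brochner-Mortensen correction, BSA normalization, and KDIGO
#' classification. The contract is fail-closed: any hard problem (missing
#' draw, below-LOQ concentration, non-decaying curve, low R-squared)
#' withholds the result with a machine-readable reason instead of emitting
#' a number.
#'
#' @param order A `"test_order"` (see [parse_order_csv()]) or a list with
#'   `patient_id`, `dose_mg`, `bsa_m2`, `injection_time` (POSIXct), and
#'   `draw_times` (POSIXct vector).
#' @param concentrations Data frame with one row per draw, columns
#'   `concentration` (ug/mL) and optionally `flag` (from
#'   [back_calculate()]), in draw order.
#' @param config A [gfr_config()].
#'
#' @return An object of class `"clearance_result"`: a list with the fit
#'   quantities, `c2`, `gfr_bm`, `gfr_normalized`, `kdigo`, `flags`,
#'   `status` (`"reported"` or `"withheld"`), and `reason` when withheld.
#' @export
compute_mgfr <- function(order, concentrations, config = gfr_config()) {
  conc_df <- as.data.frame(concentrations)
  if (!"flag" %in% names(conc_df)) conc_df$flag <- "ok"

  res <- list(patient_id = order$patient_id, dose = order$dose_mg,
              bsa = order$bsa_m2, flags = character(0),
              status = "withheld", reason = NA_character_,
              elapsed_min = NA, concentrations = conc_df$concentration,
              log_intercept = NA_real_, slope = NA_real_, beta = NA_real_,
              r_squared = NA_real_, auc_slow = NA_real_, c2 = NA_real_,
              gfr_bm = NA_real_, gfr_normalized = NA_real_,
              kdigo = NA_character_)
  class(res) <- "clearance_result"
  withhold <- function(reason) { res$reason <- reason; res }

  if (is.null(order$dose_mg) || !is.finite(order$dose_mg) ||
      order$dose_mg <= 0)
    return(withhold("invalid_dose"))
  if (is.null(order$bsa_m2) || !is.finite(order$bsa_m2) ||
      order$bsa_m2 <= 0)
    return(withhold("missing_bsa"))
  if (order$bsa_m2 < config$bsa_range[1] || order$bsa_m2 > config$bsa_range[2])
    res$flags <- c(res$flags, "bsa_out_of_range")

  n_expected <- length(order$draw_times)
  if (nrow(conc_df) != n_expected)
    return(withhold("missing_draw"))
  if (anyNA(conc_df$concentration))
    return(withhold("missing_draw"))
  if (any(conc_df$flag == "below_loq") || any(conc_df$concentration <= 0))
    return(withhold("below_loq"))
  if (any(conc_df$flag == "above_range"))
    res$flags <- c(res$flags, "above_range_redilute")

  el <- as.numeric(difftime(order$draw_times, order$injection_time,
                            units = "mins"))
  if (any(el <= 0) || is.unsorted(el, strictly = TRUE))
    return(withhold("invalid_draw_times"))
  res$elapsed_min <- el

  fit <- tryCatch(
    fit_slow_compartment(el, conc_df$concentration,
                         min_time = config$min_draw_time),
    error = function(e) e)
  if (inherits(fit, "error")) return(withhold("non_decaying_curve"))
  res$flags <- c(res$flags, fit$flags)
  res$log_intercept <- fit$log_intercept
  res$slope <- fit$slope
  res$beta <- fit$beta
  res$r_squared <- fit$r_squared

  si <- slope_intercept_clearance(fit$log_intercept, fit$slope, order$dose_mg)
  res$auc_slow <- si$auc_slow
  res$c2 <- si$c2
  gfr <- bm_correct(si$c2)
  res$flags <- c(res$flags, attr(gfr, "flags"))
  res$gfr_bm <- as.numeric(gfr)
  res$gfr_normalized <- normalize_bsa(res$gfr_bm, order$bsa_m2)
  res$kdigo <- classify_kdigo(res$gfr_normalized)

  if (fit$r_squared < config$r2_threshold) {
    res$flags <- c(res$flags, "low_r_squared")
    return(withhold("low_r_squared"))
  }
  res$status <- "reported"
  res
}

#' @export
print.clearance_result <- function(x, ...) {
  cat("mGFR result for", x$patient_id, "-", x$status, "\n")
  if (x$status == "withheld")
    cat("  reason:", x$reason, "\n")
  if (is.finite(x$c2)) {
    cat(sprintf("  beta = %.6g /min, R^2 = %.4f\n", x$beta, x$r_squared))
    cat(sprintf("  C2 = %.2f mL/min, GFR(BM) = %.2f mL/min\n", x$c2, x$gfr_bm))
    cat(sprintf("  GFR = %.1f mL/min/1.73m^2 (%s)\n",
                x$gfr_normalized, x$kdigo))
  }
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}
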