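#' Limit of detection from blank statistics
#'
#' LOD = mean of the blank signal + 3 SD.
#'
#' @param mean Mean blank concentration (ug/mL).
#' @param sd Standard deviation of the blank (ug/mL), >= 0.
#' @param n Number of blank measurements (>= 2, informational).
#' @return LOD in ug/mL.
#' @export
#' @examples
#' compute_lod(0.30, 0.28)  # 1.14
compute_lod <- function(mean, sd, n = NULL) {
  if (!is.finite(mean) || !is.finite(sd) || sd < 0)
    stop("invalid blank statistics")
  if (!is.null(n) && n < 2) stop("blank n must be >= 2")
  mean + 3 * sd
}

#' Lower limit of quantification
#'
#' LOQ = max( concentration at which the between-day CV falls to the CV
#' limit, blank mean + 10 SD ). The CV criterion is evaluated on a
#' measured CV-vs-concentration profile: the crossing is located by
#' log-linear interpolation (linear in log concentration) between the
#' bracketing tested levels, since precision profiles are near-linear on a
#' log concentration axis. If every tested CV is already below the limit,
#' the CV criterion contributes the lowest tested concentration.
#'
#' @param blank_mean,blank_sd Blank statistics (ug/mL).
#' @param cv_profile Data frame with columns `concentration` (ug/mL,
#'   ascending) and `cv` (percent) from a between-day precision series.
#' @param cv_limit CV criterion in percent (default 20).
#' @return A list with `loq` (ug/mL), `loq_cv` (the CV-criterion
#'   candidate), and `loq_blank` (the blank-based candidate).
#' @export
#' @examples
#' prof <- data.frame(concentration = c(0.5, 1, 2, 5),
#'                    cv = c(18, 12, 8, 4))
#' compute_loq(0.30, 0.28, prof)
compute_loq <- function(blank_mean, blank_sd, cv_profile, cv_limit = 20) {
  if (missing(cv_profile) || is.null(cv_profile) || nrow(cv_profile) == 0)
    stop("cv_profile must contain at least one tested concentration")
  stopifnot(all(c("concentration", "cv") %in% names(cv_profile)))
  prof <- cv_profile[order(cv_profile$concentration), , drop = FALSE]
  if (any(prof$concentration <= 0)) stop("profile concentrations must be > 0")

  loq_blank <- blank_mean + 10 * blank_sd

  cvs <- prof$cv
  conc <- prof$concentration
  if (all(cvs < cv_limit)) {
    loq_cv <- conc[1]
  } else if (all(cvs >= cv_limit)) {
    loq_cv <- conc[length(conc)]
  } else {
    # highest level still at/above the limit, interpolate to the next level
    i <- max(which(cvs >= cv_limit))
    if (i == length(cvs)) {
      loq_cv <- conc[i]
    } else if (cvs[i] == cv_limit) {
      loq_cv <- conc[i]
    } else {
      f <- (cvs[i] - cv_limit) / (cvs[i] - cvs[i + 1])
      loq_cv <- exp(log(conc[i]) + f * (log(conc[i + 1]) - log(conc[i])))
    }
  }
  list(loq = max(loq_cv, loq_blank), loq_cv = loq_cv, loq_blank = loq_blank)
}

#' Precision summary for a replicate design
#'
#' Pools all replicate values of one QC level and design (within-run:
#' 5 extractions x 4 injections; between-day: 2 extractions x 2 injections
#' x 5 days) into a mean and total CV (sd/mean x 100), with the
#' acceptance verdict at the configured CV limit. Other layouts are
#' summarized identically but labeled nonstandard.
#'
#' @param values Numeric replicate measurements (ug/mL), length >= 2.
#' @param design `"within_run"` or `"between_day"` (informational label).
#' @param cv_limit Acceptance limit in percent (default 15).
#' @return A list with `n`, `mean`, `cv` (percent), `pass`, `design`, and
#'   `standard_layout` (TRUE when n matches the named design's layout).
#' @export
#' @examples
#' precision_summary(rnorm(20, 150, 4), "within_run")
precision_summary <- function(values, design = c("within_run", "between_day"),
                              cv_limit = 15) {
  design <- match.arg(design)
  values <- values[!is.na(values)]
  if (length(values) < 2) stop("need >= 2 replicate values")
  m <- mean(values)
  if (m <= 0) stop("CV undefined: mean <= 0")
  cv <- stats::sd(values) / m * 100
  list(n = length(values), mean = m, cv = cv, pass = cv <= cv_limit,
       design = design,
       standard_layout = length(values) == 20)
}

#' Carryover percentage
#'
#' From a quadruplicate low-QC injection (L1..L4) immediately following a
#' triplicate high-QC injection (H1..H3):
#' carryover = (L1 - (L3 + L4)/2) / ((H2 + H3)/2 - (L3 + L4)/2) x 100.
#' L2 and H1 are part of the injection sequence but do not enter the
#' formula. Acceptable when strictly below the limit (default 1 percent).
#'
#' @param L1,L2,L3,L4 Low-QC results in injection order (ug/mL).
#' @param H1,H2,H3 High-QC results in injection order (ug/mL).
#' @param limit Acceptance limit in percent (strict).
#' @return A list with `carryover` (percent) and `pass`.
#' @export
#' @examples
#' carryover_percent(20.5, 20.1, 20.0, 20.0, 810, 800, 800)
carryover_percent <- function(L1, L2, L3, L4, H1, H2, H3, limit = 1) {
  low_base <- (L3 + L4) / 2
  high_base <- (H2 + H3) / 2
  denom <- high_base - low_base
  if (!is.finite(denom) || denom <= 0)
    stop("invalid carryover design: high level must exceed low level")
  co <- (L1 - low_base) / denom * 100
  list(carryover = co, pass = co < limit)
}

#' Extraction recovery percentage
#'
#' Compares specimens spiked before extraction with specimens spiked after
#' extraction: recovery = mean(pre) / mean(post) x 100.
#'
#' @param pre_spike_areas Peak areas, analyte spiked before extraction.
#' @param post_spike_areas Peak areas, analyte spiked after extraction.
#' @return Recovery in percent.
#' @export
recovery_percent <- function(pre_spike_areas, post_spike_areas) {
  mp <- mean(post_spike_areas)
  if (!is.finite(mp) || mp <= 0) stop("post-spike mean must be > 0")
  mean(pre_spike_areas) / mp * 100
}

#' Matrix effect percentage
#'
#' Deviation of the serum response from the neat-solvent response for the
#' same spiked amount: (mean(serum)/mean(solvent) - 1) x 100. Zero means
#' no matrix effect; negative values indicate ion suppression.
#'
#' @param serum_areas Peak areas in spiked blank serum.
#' @param solvent_areas Peak areas in spiked blank solvent.
#' @return Percent deviation.
#' @export
matrix_effect_percent <- function(serum_areas, solvent_areas) {
  ms <- mean(solvent_areas)
  if (!is.finite(ms) || ms <= 0) stop("solvent mean must be > 0")
  (mean(serum_areas) / ms - 1) * 100
}

#' Stability check against a baseline
#'
#' Per-timepoint recovery = value / baseline x 100; the series is stable
#' only when every recovery lies inside the acceptance window (default
#' 85-115 percent).
#'
#' @param baseline Baseline measurement (> 0).
#' @param timepoint_values Measurements at later timepoints (named or not).
#' @param limits Acceptance window in percent.
#' @return A list with `recovery` (percent per timepoint) and `stable`.
#' @export
#' @examples
#' stability_check(100, c(`6h` = 98, `24h` = 103))
stability_check <- function(baseline, timepoint_values,
                            limits = c(85, 115)) {
  if (!is.finite(baseline) || baseline <= 0) stop("baseline must be > 0")
  rec <- timepoint_values / baseline * 100
  list(recovery = rec,
       stable = all(rec >= limits[1] & rec <= limits[2]))
}

#' Deming (errors-in-both-variables) regression
#'
#' Method-comparison regression allowing measurement error in both
#' methods. `error_variance_ratio` is the ratio of the y-method error
#' variance to the x-method error variance (default 1: two methods of
#' equal analytical precision); as the ratio tends to infinity the
#' estimate converges to ordinary least squares of y on x, and as it
#' tends to zero to the inverse OLS of x on y. The slope confidence
#' interval is computed by the leave-one-out jackknife, the common
#' clinical-chemistry practice; the Pearson correlation is reported
#' alongside.
#'
#' @param x,y Paired measurements from the two methods, n >= 3.
#' @param error_variance_ratio Ratio var(y errors)/var(x errors), > 0.
#' @param conf_level Confidence level for the slope interval.
#' @return A list with `slope`, `intercept`, `slope_ci` (length 2),
#'   `slope_se`, `correlation`, `n`, and `error_variance_ratio`.
#' @export
#' @examples
#' x <- c(4, 50, 250, 750)
#' deming_fit(x, 2 * x + 1)
deming_fit <- function(x, y, error_variance_ratio = 1, conf_level = 0.95) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  n <- length(x)
  if (n < 3) stop("need at least 3 paired measurements")
  if (!is.finite(error_variance_ratio) || error_variance_ratio <= 0)
    stop("error_variance_ratio must be > 0")

  est <- function(x, y) {
    sxx <- stats::var(x); syy <- stats::var(y); sxy <- stats::cov(x, y)
    if (sxx == 0 && syy == 0) stop("degenerate data: zero variance")
    lam <- error_variance_ratio
    if (sxy == 0) return(c(slope = 0, intercept = mean(y)))
    b <- (syy - lam * sxx + sqrt((syy - lam * sxx)^2 + 4 * lam * sxy^2)) /
      (2 * sxy)
    c(slope = b, intercept = mean(y) - b * mean(x))
  }
  full <- est(x, y)

  # leave-one-out jackknife on the slope
  loo <- vapply(seq_len(n), function(i) est(x[-i], y[-i])["slope"], numeric(1))
  pseudo <- n * full["slope"] - (n - 1) * loo
  se <- stats::sd(pseudo) / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  ci <- unname(full["slope"] + c(-1, 1) * tq * se)

  list(slope = unname(full["slope"]),
       intercept = unname(full["intercept"]),
       slope_ci = ci, slope_se = unname(se),
       correlation = stats::cor(x, y), n = n,
       error_variance_ratio = error_variance_ratio)
}

#' Bland-Altman agreement analysis
#'
#' Bias and 95 percent limits of agreement between paired methods. The
#' default works on absolute differences y - x; `type = "percent"` uses
#' the percent difference relative to the pairwise mean, useful when the
#' disagreement scales with concentration.
#'
#' @param x,y Paired measurements, n >= 2.
#' @param type `"absolute"` (default) or `"percent"`.
#' @return A list with `bias`, `loa_lower`, `loa_upper`, `sd_diff`,
#'   `differences`, and `type`.
#' @export
#' @examples
#' bland_altman(c(1, 2, 3), c(1.1, 2.1, 3.1))
bland_altman <- function(x, y, type = c("absolute", "percent")) {
  type <- match.arg(type)
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- if (type == "absolute") y - x else (y - x) / ((x + y) / 2) * 100
  bias <- mean(d)
  s <- stats::sd(d)
  list(bias = bias, loa_lower = bias - 1.96 * s, loa_upper = bias + 1.96 * s,
       sd_diff = s, differences = d, type = type)
}

#' Method-validation summary
#'
#' Convenience aggregator assembling the individual validation statistics
#' into one record, mirroring how a validation report is tabulated.
#'
#' @param blank List with `mean`, `sd`, `n`.
#' @param cv_profile CV-vs-concentration data frame for [compute_loq()].
#' @param precision Named list of replicate-value vectors; names are
#'   `"<level>_<design>"` labels, each summarized by [precision_summary()].
#' @param carryover List of the seven carryover injections (L1..L4,
#'   H1..H3) or NULL.
#' @param comparison List with paired `x`, `y` vectors for Deming and
#'   Bland-Altman, or NULL.
#' @param config A [gfr_config()].
#' @return A list of class `"validation_summary"`.
#' @export
validation_summary <- function(blank, cv_profile = NULL, precision = NULL,
                               carryover = NULL, comparison = NULL,
                               config = gfr_config()) {
  out <- list(lod = compute_lod(blank$mean, blank$sd, blank$n))
  if (!is.null(cv_profile))
    out$loq <- compute_loq(blank$mean, blank$sd, cv_profile)
  if (!is.null(precision)) {
    out$precision <- do.call(rbind, lapply(names(precision), function(nm) {
      design <- if (grepl("between", nm)) "between_day" else "within_run"
      s <- precision_summary(precision[[nm]], design,
                             cv_limit = config$cv_limit)
      data.frame(label = nm, n = s$n, mean = s$mean, cv = s$cv,
                 pass = s$pass, stringsAsFactors = FALSE)
    }))
  }
  if (!is.null(carryover))
    out$carryover <- do.call(carryover_percent,
                             c(carryover, list(limit = config$carryover_limit)))
  if (!is.null(comparison)) {
    out$deming <- deming_fit(comparison$x, comparison$y)
    out$bland_altman <- bland_altman(comparison$x, comparison$y)
  }
  class(out) <- "validation_summary"
  out
}

#' @export
print.validation_summary <- function(x, ...) {
  cat("Method-validation summary\n")
  cat(sprintf("  LOD: %.3g ug/mL\n", x$lod))
  if (!is.null(x$loq))
    cat(sprintf("  LOQ: %.3g ug/mL (CV criterion %.3g, blank+10SD %.3g)\n",
                x$loq$loq, x$loq$loq_cv, x$loq$loq_blank))
  if (!is.null(x$precision)) {
    cat("  precision:\n")
    for (i in seq_len(nrow(x$precision)))
      cat(sprintf("    %s: mean %.4g, CV %.2f%% (%s)\n",
                  x$precision$label[i], x$precision$mean[i],
                  x$precision$cv[i],
                  if (x$precision$pass[i]) "pass" else "FAIL"))
  }
  if (!is.null(x$carryover))
    cat(sprintf("  carryover: %.3f%% (%s)\n", x$carryover$carryover,
                if (x$carryover$pass) "pass" else "FAIL"))
  if (!is.null(x$deming))
    cat(sprintf("  Deming slope %.3f (CI %.3f-%.3f), r = %.4f\n",
                x$deming$slope, x$deming$slope_ci[1], x$deming$slope_ci[2],
                x$deming$correlation))
  invisible(x)
}
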