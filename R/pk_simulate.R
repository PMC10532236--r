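#' Two-compartment disposition parameters for a bolus dose
#'
#' Derives the macro constants of the biexponential plasma decay
#' C(t) = A exp(-alpha t) + B exp(-beta t) from the micro parameters of a
#' two-compartment model with first-order elimination from the central
#' compartment: k10 = CL/V1, k12 = Q/V1, k21 = Q/V2, with
#' alpha + beta = k10 + k12 + k21 and alpha * beta = k10 * k21.
#'
#' After a bolus, the fast exponent alpha describes distribution into the
#' peripheral compartment and the slow exponent beta the renal elimination
#' phase. The macro constants are always consistent with the clearance:
#' dose / (A/alpha + B/beta) = CL.
#'
#' @param V1 Central volume of distribution (L).
#' @param V2 Peripheral volume (L).
#' @param Q Intercompartmental clearance (L/min).
#' @param CL True (renal) clearance (L/min); the ground-truth GFR.
#' @param dose Administered dose (mg).
#'
#' @return An object of class `"pk_parameters"`: a list with the micro
#'   constants, the macro constants `A`, `B` (mg/L) and `alpha`, `beta`
#'   (1/min), and the dose.
#' @export
#' @examples
#' p <- pk_parameters(V1 = 6.5, V2 = 5.5, Q = 0.1, CL = 0.1, dose = 3235.5)
#' p$dose / (p$A / p$alpha + p$B / p$beta)  # equals CL
pk_parameters <- function(V1 = 6.5, V2 = 5.5, Q = 0.1, CL, dose = 3235.5) {
  vals <- c(V1 = V1, V2 = V2, Q = Q, CL = CL, dose = dose)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all of V1, V2, Q, CL, dose must be finite and > 0")
  k10 <- CL / V1
  k12 <- Q / V1
  k21 <- Q / V2
  s <- k10 + k12 + k21
  disc <- s^2 - 4 * k10 * k21
  if (disc <= 0) stop("degenerate rate constants: quadratic discriminant <= 0")
  alpha <- (s + sqrt(disc)) / 2
  beta <- (s - sqrt(disc)) / 2
  A <- (dose / V1) * (alpha - k21) / (alpha - beta)
  B <- (dose / V1) * (k21 - beta) / (alpha - beta)
  structure(list(V1 = V1, V2 = V2, Q = Q, CL = CL, dose = dose,
                 k10 = k10, k12 = k12, k21 = k21,
                 alpha = alpha, beta = beta, A = A, B = B),
            class = "pk_parameters")
}

#' @export
print.pk_parameters <- function(x, ...) {
  cat("Two-compartment bolus disposition\n")
  cat(sprintf("  V1 = %.3g L, V2 = %.3g L, Q = %.3g L/min, CL = %.4g L/min\n",
              x$V1, x$V2, x$Q, x$CL))
  cat(sprintf("  alpha = %.5g /min, beta = %.5g /min (t1/2 = %.1f / %.1f min)\n",
              x$alpha, x$beta, log(2) / x$alpha, log(2) / x$beta))
  cat(sprintf("  A = %.4g mg/L, B = %.4g mg/L, dose = %.4g mg\n",
              x$A, x$B, x$dose))
  invisible(x)
}

#' Biexponential plasma concentration at time t
#'
#' @param params A `"pk_parameters"` object.
#' @param t Time after the bolus (min); vectorized.
#' @return Concentration (ug/mL, equivalently mg/L).
#' @export
pk_concentration <- function(params, t) {
  stopifnot(inherits(params, "pk_parameters"))
  params$A * exp(-params$alpha * t) + params$B * exp(-params$beta * t)
}

#' Simulate a sampled iohexol concentration-time profile
#'
#' Evaluates the biexponential decay at the requested draw times and adds
#' proportional Gaussian measurement noise: noisy = true * (1 + eps) with
#' eps ~ N(0, noise_cv). Draws that would be non-positive are redrawn
#' (truncation at zero is never applied silently); the number of redraws is
#' recorded and a warning is emitted if any occurred.
#'
#' @param params A `"pk_parameters"` object.
#' @param sample_times Draw times in minutes, strictly ascending, all > 0.
#'   Default is the three-point 120/180/240 min schedule.
#' @param noise_cv Proportional noise coefficient of variation (fraction,
#'   e.g. 0.04 for 4 percent). Zero gives the noise-free profile.
#' @param seed Optional integer seed; the caller's RNG state is restored.
#'
#' @return A list of class `"simulated_profile"` with `dose`,
#'   `sample_times`, `true_concentrations`, `noisy_concentrations`,
#'   `noise_cv`, `rng_seed`, and `n_redrawn`.
#' @export
#' @examples
#' p <- pk_parameters(CL = 0.1)
#' simulate_profile(p, noise_cv = 0.04, seed = 1)
simulate_profile <- function(params, sample_times = c(120, 180, 240),
                             noise_cv = 0.04, seed = NULL) {
  stopifnot(inherits(params, "pk_parameters"))
  if (length(sample_times) == 0) stop("sample_times must be non-empty")
  if (any(sample_times <= 0)) stop("sample_times must be > 0")
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("sample_times must be strictly ascending")
  if (!is.finite(noise_cv) || noise_cv < 0) stop("noise_cv must be >= 0")

  true_c <- pk_concentration(params, sample_times)
  n_redrawn <- 0L
  noisy <- with_local_seed(seed, {
    if (noise_cv == 0) true_c else {
      out <- true_c * (1 + stats::rnorm(length(true_c), 0, noise_cv))
      while (any(bad <- out <= 0)) {
        n_redrawn <- n_redrawn + sum(bad)
        out[bad] <- true_c[bad] * (1 + stats::rnorm(sum(bad), 0, noise_cv))
      }
      out
    }
  })
  if (n_redrawn > 0)
    warning(sprintf("%d non-positive noise draw(s) redrawn", n_redrawn))
  structure(list(dose = params$dose, sample_times = sample_times,
                 true_concentrations = true_c,
                 noisy_concentrations = noisy,
                 noise_cv = noise_cv, rng_seed = seed,
                 n_redrawn = n_redrawn),
            class = "simulated_profile")
}

#' Simulate a raw instrument batch from concentration profiles
#'
#' Inverts the quantitation model to produce raw peak areas: for a specimen
#' of concentration c, area_ratio = slope * c + intercept, the internal
#' standard area is the configured nominal, and the analyte area is
#' area_ratio * istd_area perturbed by proportional Gaussian noise on the
#' ratio. The batch carries blanks, the full calibrator series, the QC
#' levels, and one row per patient draw, in the same CSV dialect that
#' [parse_instrument_csv()] reads. Ground truth is returned alongside for
#' use as a test oracle.
#'
#' @param profiles Named list of `"simulated_profile"` objects, one per
#'   patient; names are patient identifiers used to form draw barcodes
#'   (`<patient>-1`, `<patient>-2`, ...).
#' @param calibration_truth List with `slope` (> 0) and `intercept` of the
#'   true area-ratio-vs-concentration line. Default slope 0.01/ (ug/mL),
#'   intercept 0.
#' @param area_noise_cv Proportional noise on the simulated area ratio.
#' @param seed Optional integer seed.
#' @param istd_area Nominal internal-standard peak area (arbitrary units).
#' @param n_blanks Number of blank rows.
#' @param config A [gfr_config()] supplying calibrator and QC levels.
#'
#' @return A list with `batch`: data frame of (barcode, role,
#'   nominal_concentration, analyte_area, istd_area); and `truth`: data
#'   frame of (barcode, true_concentration).
#' @export
simulate_instrument_batch <- function(profiles,
                                      calibration_truth = list(slope = 0.01,
                                                               intercept = 0),
                                      area_noise_cv = 0.04,
                                      seed = NULL,
                                      istd_area = 1e5,
                                      n_blanks = 2,
                                      config = gfr_config()) {
  stopifnot(is.list(calibration_truth),
            is.numeric(calibration_truth$slope))
  if (calibration_truth$slope <= 0) stop("calibration_truth$slope must be > 0")
  if (!is.finite(area_noise_cv) || area_noise_cv < 0)
    stop("area_noise_cv must be >= 0")
  if (is.null(names(profiles)) && length(profiles) > 0)
    names(profiles) <- sprintf("PT%03d", seq_along(profiles))

  rows <- list()
  add <- function(barcode, role, nominal, conc) {
    rows[[length(rows) + 1L]] <<- data.frame(
      barcode = barcode, role = role,
      nominal_concentration = nominal,
      true_concentration = conc,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(n_blanks))
    add(sprintf("BLK-%02d", i), "blank", NA_real_, 0)
  for (i in seq_along(config$calibrator_levels))
    add(sprintf("CAL-%02d", i), "calibrator",
        config$calibrator_levels[i], config$calibrator_levels[i])
  for (i in seq_along(config$qc_levels))
    add(sprintf("QC-%02d", i), "qc",
        config$qc_levels[i], config$qc_levels[i])
  for (id in names(profiles)) {
    pr <- profiles[[id]]
    stopifnot(inherits(pr, "simulated_profile"))
    for (j in seq_along(pr$sample_times))
      add(sprintf("%s-%d", id, j), "patient", NA_real_,
          pr$noisy_concentrations[j])
  }
  tab <- do.call(rbind, rows)

  ratio_true <- calibration_truth$slope * tab$true_concentration +
    calibration_truth$intercept
  ratio <- with_local_seed(seed, {
    if (area_noise_cv == 0) ratio_true else {
      eps <- stats::rnorm(nrow(tab), 0, area_noise_cv)
      # blanks carry additive-scale noise at the level of the lowest
      # calibrator's noise so blank areas are not identically zero
      base <- pmax(ratio_true,
                   calibration_truth$slope * min(config$calibrator_levels) * 0.05)
      pmax(ratio_true + base * eps, 0)
    }
  })
  batch <- data.frame(barcode = tab$barcode, role = tab$role,
                      nominal_concentration = tab$nominal_concentration,
                      analyte_area = ratio * istd_area,
                      istd_area = istd_area,
                      stringsAsFactors = FALSE)
  truth <- data.frame(barcode = tab$barcode,
                      true_concentration = tab$true_concentration,
                      stringsAsFactors = FALSE)
  list(batch = batch, truth = truth)
}

#' Simulate a complete seeded mGFR study
#'
#' Convenience wrapper producing everything the downstream pipeline needs:
#' per-patient two-compartment profiles at the protocol draw schedule, the
#' raw instrument batch, the matching test-order table (with injection and
#' draw timestamps and per-patient BSA), and the ground truth.
#'
#' @param n_patients Number of simulated patients.
#' @param gfr True clearance(s) in mL/min; recycled across patients.
#' @param bsa Body surface area(s) in m^2; recycled.
#' @param noise_cv Proportional concentration noise (fraction).
#' @param area_noise_cv Proportional area-ratio noise (fraction).
#' @param seed Integer seed governing all randomness.
#' @param config A [gfr_config()].
#' @param V1,V2,Q Two-compartment micro parameters (L, L, L/min).
#' @param injection_time Timestamp of the bolus for patient 1; subsequent
#'   patients are staggered by 5 min.
#'
#' @return A list with `batch`, `orders`, `truth` data frames and
#'   `profiles` (the simulated profiles).
#' @export
#' @examples
#' study <- simulate_study(n_patients = 2, gfr = c(90, 110), seed = 7)
#' head(study$batch)
simulate_study <- function(n_patients = 3, gfr = 100, bsa = 1.9,
                           noise_cv = 0.04, area_noise_cv = 0.04,
                           seed = NULL, config = gfr_config(),
                           V1 = 6.5, V2 = 5.5, Q = 0.1,
                           injection_time = as.POSIXct("2024-03-01 08:00:00",
                                                       tz = "UTC")) {
  stopifnot(n_patients >= 1, all(gfr > 0), all(bsa > 0))
  gfr <- rep_len(gfr, n_patients)
  bsa <- rep_len(bsa, n_patients)
  dose <- config$default_volume * config$formulation_concentration

  with_local_seed(seed, {
    profiles <- list()
    orders <- list()
    for (i in seq_len(n_patients)) {
      id <- sprintf("PT%03d", i)
      params <- pk_parameters(V1 = V1, V2 = V2, Q = Q,
                              CL = gfr[i] / 1000, dose = dose)
      profiles[[id]] <- simulate_profile(params, config$nominal_times,
                                         noise_cv = noise_cv, seed = NULL)
      inj <- injection_time + (i - 1) * 300
      draws <- inj + config$nominal_times * 60
      orders[[i]] <- data.frame(
        patient_id = id,
        injected_volume_ml = config$default_volume,
        formulation_mg_per_ml = config$formulation_concentration,
        dose_mg = NA_real_,
        bsa_m2 = bsa[i],
        injection_time = format(inj, "%Y-%m-%dT%H:%M:%S"),
        stringsAsFactors = FALSE)
      for (j in seq_along(draws)) {
        orders[[i]][[sprintf("barcode_%d", j)]] <- sprintf("%s-%d", id, j)
        orders[[i]][[sprintf("time_%d", j)]] <-
          format(draws[j], "%Y-%m-%dT%H:%M:%S")
      }
    }
    sim <- simulate_instrument_batch(profiles,
                                     area_noise_cv = area_noise_cv,
                                     seed = NULL, config = config)
    truth <- sim$truth
    truth$true_CL <- NA_real_
    for (i in seq_len(n_patients))
      truth$true_CL[grepl(sprintf("^PT%03d-", i), truth$barcode)] <- gfr[i]
    list(batch = sim$batch, orders = do.call(rbind, orders),
         truth = truth, profiles = profiles)
  })
}
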