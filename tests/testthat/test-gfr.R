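test_that("worked profile: 60-min half-life gives the hand-computed clearance", {
  wp <- worked_profile()
  f <- fit_slow_compartment(wp$t, wp$conc)
  expect_equal(f$slope, -log(2) / 60, tolerance = 1e-10)
  expect_equal(f$beta, wp$beta, tolerance = 1e-10)
  expect_equal(exp(f$log_intercept), 800, tolerance = 1e-8)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  si <- slope_intercept_clearance(f$log_intercept, f$slope, wp$dose)
  expect_equal(si$c0, 800, tolerance = 1e-8)
  expect_equal(si$auc_slow, 800 * 60 / log(2), tolerance = 1e-6)
  expect_equal(si$c2, 3235.5 / (800 / (log(2) / 60)) * 1000,
               tolerance = 1e-10)
  expect_equal(si$c2, 46.72, tolerance = 1e-4)
  expect_equal(bm_correct(si$c2), 43.63, tolerance = 1e-3)

  # quadrature oracle: AUC of the extrapolated monoexponential
  auc_num <- stats::integrate(function(t) 800 * exp(-wp$beta * t), 0, Inf,
                              rel.tol = 1e-10)$value
  expect_equal(si$auc_slow, auc_num, tolerance = 1e-3)
})

test_that("clearance is linear in dose", {
  wp <- worked_profile()
  f <- fit_slow_compartment(wp$t, wp$conc)
  c2_1 <- slope_intercept_clearance(f$log_intercept, f$slope, wp$dose)$c2
  c2_2 <- slope_intercept_clearance(f$log_intercept, f$slope, 2 * wp$dose)$c2
  expect_equal(c2_2, 2 * c2_1, tolerance = 1e-12)
})

test_that("slow-compartment fit guards against bad inputs", {
  expect_error(fit_slow_compartment(c(120, 180), c(100, 0)), "> 0")
  expect_error(fit_slow_compartment(c(120, 180, 240), c(50, 100, 200)),
               "non-decaying")
  expect_error(fit_slow_compartment(120, 100), "at least 2")
  # imperfect decay is fit but with R^2 < 1
  f <- fit_slow_compartment(c(120, 180, 240), c(100, 100, 50))
  expect_lt(f$r_squared, 1)
  # draws before 120 min are flagged as distribution-phase contaminated
  f2 <- fit_slow_compartment(c(60, 180, 240), c(300, 100, 50))
  expect_true("early_draw" %in% f2$flags)
})

test_that("BM correction matches its quadratic and its analytic properties", {
  expect_equal(bm_correct(0), 0)
  expect_equal(bm_correct(100), 86.8978, tolerance = 1e-10)
  expect_equal(bm_correct(46.72), 0.990778 * 46.72 - 0.001218 * 46.72^2,
               tolerance = 1e-12)
  # strictly increasing on [0, 400] and always below c2 on (0, 400]
  g <- seq(0, 400, by = 1)
  v <- bm_correct(g)
  expect_true(all(diff(v) > 0))
  expect_true(all(v[-1] < g[-1]))
  expect_error(bm_correct(-5), ">= 0")
  expect_true("c2_out_of_range" %in% attr(bm_correct(450), "flags"))
})

test_that("BSA normalization and KDIGO classification", {
  expect_equal(normalize_bsa(86.8978, 1.73), 86.8978)
  expect_equal(normalize_bsa(86.8978, 2.0), 86.8978 * 1.73 / 2, tolerance = 1e-12)
  expect_equal(normalize_bsa(86.8978, 2.0), 75.17, tolerance = 1e-3)
  expect_equal(normalize_bsa(50, 0.865), 100, tolerance = 1e-9)
  expect_error(normalize_bsa(80, 0), "> 0")
  expect_equal(classify_kdigo(c(59.9, 60, 75, 89.99, 90, 120)),
               c("exclusion", "intermediate", "intermediate",
                 "intermediate", "acceptance", "acceptance"))
})

test_that("compute_mgfr composes the worked example end to end", {
  ord <- make_order(bsa = 2.0)
  conc <- data.frame(concentration = c(200, 100, 50))
  res <- compute_mgfr(ord, conc)
  expect_equal(res$status, "reported")
  expect_equal(res$c2, 46.72, tolerance = 1e-4)
  expect_equal(res$gfr_bm, 43.63, tolerance = 1e-3)
  expect_equal(res$gfr_normalized, res$gfr_bm * 1.73 / 2.0, tolerance = 1e-12)
  expect_equal(res$kdigo, "exclusion")
})

test_that("time-origin invariance: shifting all timestamps changes nothing", {
  conc <- data.frame(concentration = c(180, 95, 52))
  r1 <- compute_mgfr(make_order(), conc)
  shifted <- make_order(t0 = as.POSIXct("2025-11-30 23:41:07", tz = "UTC"))
  r2 <- compute_mgfr(shifted, conc)
  expect_equal(r1$gfr_normalized, r2$gfr_normalized, tolerance = 1e-12)
  expect_equal(r1$c2, r2$c2, tolerance = 1e-12)
  expect_equal(r1$r_squared, r2$r_squared, tolerance = 1e-12)
})

test_that("two-point and three-point fits agree exactly on monoexponential data", {
  wp <- worked_profile()
  f3 <- fit_slow_compartment(wp$t, wp$conc)
  f2 <- fit_slow_compartment(wp$t[c(1, 3)], wp$conc[c(1, 3)])
  expect_equal(f3$slope, f2$slope, tolerance = 1e-12)
  expect_equal(f3$log_intercept, f2$log_intercept, tolerance = 1e-12)
  expect_equal(f3$r_squared, 1)
})

test_that("the result is withheld, never defaulted, on any hard failure", {
  ord <- make_order()
  ok <- data.frame(concentration = c(200, 100, 50))
  # missing draw
  r <- compute_mgfr(ord, ok[1:2, , drop = FALSE])
  expect_equal(r$status, "withheld"); expect_equal(r$reason, "missing_draw")
  expect_true(is.na(r$gfr_normalized))
  # below-LOQ concentration is a hard withhold (no imputation at n = 3)
  r <- compute_mgfr(ord, data.frame(concentration = c(200, 100, 2),
                                    flag = c("ok", "ok", "below_loq")))
  expect_equal(r$reason, "below_loq"); expect_true(is.na(r$gfr_normalized))
  # increasing concentrations
  r <- compute_mgfr(ord, data.frame(concentration = c(50, 100, 200)))
  expect_equal(r$reason, "non_decaying_curve")
  # low R^2 withholds but keeps the diagnostics
  r <- compute_mgfr(ord, data.frame(concentration = c(200, 150, 30)))
  expect_equal(r$status, "withheld")
  expect_equal(r$reason, "low_r_squared")
  expect_lt(r$r_squared, 0.98)
  expect_true(is.finite(r$c2))  # diagnostics retained for review
  # missing BSA / bad dose
  ord2 <- make_order(); ord2$bsa_m2 <- NA
  expect_equal(compute_mgfr(ord2, ok)$reason, "missing_bsa")
  ord3 <- make_order(dose_mg = -1)
  expect_equal(compute_mgfr(ord3, ok)$reason, "invalid_dose")
  # draw before injection
  ord4 <- make_order()
  ord4$draw_times[1] <- ord4$injection_time - 60
  expect_equal(compute_mgfr(ord4, ok)$reason, "invalid_draw_times")
})

test_that("zero-noise recovery of true clearance is within 10% across the grid", {
  for (gfr in c(60, 80, 100, 120)) {
    p <- pk_parameters(CL = gfr / 1000)
    pr <- simulate_profile(p, noise_cv = 0)
    ord <- make_order(dose_mg = p$dose)
    res <- compute_mgfr(ord, data.frame(concentration = pr$true_concentrations))
    expect_equal(res$status, "reported")
    expect_lt(abs(res$gfr_bm - gfr) / gfr, 0.10)
  }
})

test_that("noisy recovery: median absolute relative error within 10%", {
  # 4% proportional concentration noise, 150 seeded replicates per level
  set.seed(77)
  for (gfr in c(60, 100)) {
    p <- pk_parameters(CL = gfr / 1000)
    ord <- make_order(dose_mg = p$dose)
    errs <- replicate(150, {
      pr <- simulate_profile(p, noise_cv = 0.04)
      res <- compute_mgfr(ord, data.frame(concentration = pr$noisy_concentrations))
      abs(res$gfr_bm - gfr) / gfr
    })
    expect_lte(stats::median(errs), 0.10)
  }
})
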