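test_that("LOD is blank mean + 3 SD, with linear scale behavior", {
  expect_equal(compute_lod(0.30, 0.28, n = 20), 1.14, tolerance = 1e-12)
  expect_equal(compute_lod(0, 0), 0)
  expect_equal(compute_lod(1, 0.5), 2.5)
  # scaling property: LOD(k*m, k*s) = k*LOD(m, s)
  for (k in c(0.5, 2, 10))
    expect_equal(compute_lod(k * 0.30, k * 0.28), k * 1.14, tolerance = 1e-12)
  expect_error(compute_lod(0.3, -1), "invalid")
  expect_error(compute_lod(0.3, 0.28, n = 1), "n must be >= 2")
})

test_that("LOQ takes the greater of the CV criterion and blank mean + 10 SD", {
  # all CVs already below 20%: CV criterion contributes the lowest tested
  # level and the blank term dominates (0.30 + 10 x 0.28 = 3.10)
  prof <- data.frame(concentration = c(0.5, 1, 2, 5), cv = c(15, 12, 8, 4))
  r <- compute_loq(0.30, 0.28, prof)
  expect_equal(r$loq_cv, 0.5)
  expect_equal(r$loq_blank, 3.10, tolerance = 1e-12)
  expect_equal(r$loq, 3.10, tolerance = 1e-12)
  # exact 20% crossing at a tested level
  prof2 <- data.frame(concentration = c(1, 2, 5), cv = c(30, 20, 10))
  r2 <- compute_loq(0.05, 0.05, prof2)
  expect_equal(r2$loq_cv, 2)
  expect_equal(r2$loq, 2)  # blank term 0.55 is smaller
  # blank term larger than the crossing wins
  r3 <- compute_loq(1.0, 0.5, prof2)
  expect_equal(r3$loq, 6.0)
  # interpolated crossing lies between the bracketing levels
  prof4 <- data.frame(concentration = c(1, 4), cv = c(30, 10))
  r4 <- compute_loq(0, 0, prof4)
  expect_gt(r4$loq_cv, 1); expect_lt(r4$loq_cv, 4)
  # log-linear interpolation: CV 20 is halfway between 30 and 10, so the
  # crossing sits at the geometric midpoint of 1 and 4
  expect_equal(r4$loq_cv, 2, tolerance = 1e-9)
  expect_error(compute_loq(0.3, 0.28, data.frame()), "at least one")
})

test_that("precision summary pools replicates into mean and total CV", {
  expect_equal(precision_summary(rep(150, 20), "within_run")$cv, 0)
  s <- precision_summary(c(100, 110, 90, 104), "between_day")
  expect_equal(s$mean, 101)
  expect_equal(s$cv, stats::sd(c(100, 110, 90, 104)) / 101 * 100,
               tolerance = 1e-12)
  expect_false(s$standard_layout)
  # generative 4.4% CV (QC-high-like) is recovered within Monte-Carlo bounds
  set.seed(55)
  cvs <- replicate(200, precision_summary(800 * (1 + rnorm(20, 0, 0.044)))$cv)
  expect_equal(mean(cvs), 4.4, tolerance = 0.15)
  expect_true(all(cvs < 15))  # comfortably passing the acceptance rule
  # threshold boundary
  vals <- c(85, 100, 115, 100, 130)
  s2 <- precision_summary(vals)
  expect_gt(s2$cv, 15); expect_false(s2$pass)
  expect_error(precision_summary(c(1, -3)), "mean <= 0")
  expect_error(precision_summary(5), ">= 2")
})

test_that("carryover follows the injection-sequence formula", {
  # no carryover: L1 equals the mean of L3/L4
  expect_equal(carryover_percent(20, 20, 20, 20, 810, 800, 800)$carryover, 0)
  # direct arithmetic
  r <- carryover_percent(20.5, 20.2, 20.0, 20.0, 805, 800, 800)
  expect_equal(r$carryover, 0.5 / 780 * 100, tolerance = 1e-12)
  expect_equal(r$carryover, 0.0641, tolerance = 1e-3)
  expect_true(r$pass)
  # boundary: exactly 1% fails the strict < 1% rule
  r2 <- carryover_percent(28, 21, 20, 20, 820, 820, 820)
  expect_equal(r2$carryover, 1.0, tolerance = 1e-12)
  expect_false(r2$pass)
  # L2 and H1 never enter the formula
  r3 <- carryover_percent(20.5, 999, 20.0, 20.0, -999, 800, 800)
  expect_equal(r3$carryover, r$carryover, tolerance = 1e-12)
  # degenerate design: high not above low
  expect_error(carryover_percent(20, 20, 20, 20, 20, 20, 20), "invalid")
  # affine invariance: adding a common offset to every concentration and
  # rescaling by k leaves the percentage unchanged
  base <- c(20.5, 20.2, 20.0, 20.0, 805, 800, 800)
  for (k in c(0.5, 3)) {
    sc <- as.list(base * k)
    expect_equal(do.call(carryover_percent, sc)$carryover, r$carryover,
                 tolerance = 1e-12)
  }
})

test_that("recovery, matrix effect, and stability are the stated ratios", {
  expect_equal(recovery_percent(c(100, 102), c(100, 102)), 100)
  expect_equal(recovery_percent(0.99 * c(500, 510, 490), c(500, 510, 490)), 99,
               tolerance = 1e-12)
  expect_equal(recovery_percent(50, 100), 50)
  expect_error(recovery_percent(10, 0), "> 0")
  expect_equal(matrix_effect_percent(c(100, 100), c(100, 100)), 0)
  expect_equal(matrix_effect_percent(110, 100), 10, tolerance = 1e-12)
  expect_equal(matrix_effect_percent(90, 100), -10, tolerance = 1e-12)
  s <- stability_check(100, c(100, 100, 100))
  expect_true(s$stable); expect_equal(unname(s$recovery), c(100, 100, 100))
  expect_false(stability_check(100, c(100, 84.9))$stable)
  expect_true(stability_check(200, c(198, 204, 194))$stable)  # 0/6/24 h series
  expect_error(stability_check(0, 100), "> 0")
})

test_that("Deming regression recovers exact lines for any variance ratio", {
  x <- c(4, 20, 150, 400, 755)
  for (ratio in c(0.25, 1, 4)) {
    d <- deming_fit(x, x, error_variance_ratio = ratio)
    expect_equal(d$slope, 1, tolerance = 1e-9)
    expect_equal(d$intercept, 0, tolerance = 1e-9)
    d2 <- deming_fit(x, 2 * x + 1, error_variance_ratio = ratio)
    expect_equal(d2$slope, 2, tolerance = 1e-9)
    expect_equal(d2$intercept, 1, tolerance = 1e-9)
  }
  expect_error(deming_fit(c(1, 2), c(1, 2)), "at least 3")
  expect_error(deming_fit(rep(1, 5), rep(2, 5)), "degenerate")
})

test_that("Deming limits: ratio -> Inf gives OLS of y on x, -> 0 the inverse", {
  set.seed(13)
  x <- seq(5, 750, length.out = 25)
  y <- 0.96 * x + rnorm(25, 0, 8)
  ols <- unname(stats::coef(stats::lm(y ~ x))[2])
  inv <- 1 / unname(stats::coef(stats::lm(x ~ y))[2])
  expect_equal(deming_fit(x, y, error_variance_ratio = 1e8)$slope, ols,
               tolerance = 1e-4)
  expect_equal(deming_fit(x, y, error_variance_ratio = 1e-8)$slope, inv,
               tolerance = 1e-4)
  # equal-variance estimate lies between the two regression slopes
  mid <- deming_fit(x, y)$slope
  expect_gte(mid, min(ols, inv)); expect_lte(mid, max(ols, inv))
})

test_that("Deming slope is scale-equivariant", {
  set.seed(14)
  x <- seq(10, 500, length.out = 20) + rnorm(20, 0, 5)
  y <- 0.95 * x + rnorm(20, 0, 5)
  base <- deming_fit(x, y, error_variance_ratio = 1)
  for (k in c(0.5, 3)) {
    scaled <- deming_fit(x, k * y, error_variance_ratio = k^2)
    expect_equal(scaled$slope, k * base$slope, tolerance = 1e-9)
  }
})

test_that("jackknife CI covers a known method-comparison slope", {
  # equal-variance simulation around y = 0.957x over the assay range,
  # n = 40 pairs as in a typical split-specimen comparison
  set.seed(99)
  true_slope <- 0.957
  cover <- replicate(200, {
    truth <- exp(runif(40, log(4), log(755)))
    x <- truth + rnorm(40, 0, 6)
    y <- true_slope * truth + rnorm(40, 0, 6)
    ci <- deming_fit(x, y, error_variance_ratio = 1)$slope_ci
    ci[1] <= true_slope && true_slope <= ci[2]
  })
  expect_gte(mean(cover), 0.90)
})

test_that("Bland-Altman bias and limits of agreement", {
  x <- c(10, 50, 200, 600)
  r <- bland_altman(x, x)
  expect_equal(r$bias, 0); expect_equal(r$loa_lower, 0)
  expect_equal(r$loa_upper, 0)
  r2 <- bland_altman(x, x + 5)
  expect_equal(r2$bias, 5); expect_equal(r2$loa_upper - r2$loa_lower, 0)
  # seeded noisy pairs: about 95% of differences inside the limits
  set.seed(8)
  xx <- runif(2000, 10, 700)
  yy <- xx + rnorm(2000, 2, 10)
  r3 <- bland_altman(xx, yy)
  inside <- mean(r3$differences >= r3$loa_lower &
                 r3$differences <= r3$loa_upper)
  expect_equal(inside, 0.95, tolerance = 0.02)
  expect_equal(r3$bias, 2, tolerance = 0.5)
  # percent mode
  rp <- bland_altman(c(100, 200), c(110, 220), type = "percent")
  expect_equal(rp$bias, mean(c(10 / 105, 20 / 210) * 100), tolerance = 1e-9)
  expect_error(bland_altman(1:3, 1:4), "lengths differ")
})

test_that("validation_summary aggregates the battery", {
  set.seed(4)
  vs <- validation_summary(
    blank = list(mean = 0.30, sd = 0.28, n = 20),
    cv_profile = data.frame(concentration = c(0.5, 1, 2, 5),
                            cv = c(25, 15, 8, 4)),
    precision = list(high_within = 800 * (1 + rnorm(20, 0, 0.044)),
                     medium_between = 150 * (1 + rnorm(20, 0, 0.027))),
    carryover = list(L1 = 20.5, L2 = 20.2, L3 = 20, L4 = 20,
                     H1 = 805, H2 = 800, H3 = 800),
    comparison = list(x = c(4, 50, 250, 750), y = c(4, 50, 250, 750) * 0.96))
  expect_equal(vs$lod, 1.14, tolerance = 1e-12)
  expect_gte(vs$loq$loq, vs$loq$loq_blank)
  expect_equal(nrow(vs$precision), 2)
  expect_true(all(vs$precision$pass))
  expect_true(vs$carryover$pass)
  expect_equal(vs$deming$slope, 0.96, tolerance = 1e-9)
  expect_s3_class(vs, "validation_summary")
  expect_output(print(vs), "LOD")
})
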