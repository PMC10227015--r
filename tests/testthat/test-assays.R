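# Assay estimators: Tm, velocities, IC50 with censoring, ITC fits.

test_that("Tm is recovered from noiseless and noisy Boltzmann curves", {
  clean <- simulate_melt_curve(tm = 50, amplitude = 1, slope = 1, noise_sd = 0)
  expect_equal(as.numeric(melting_temperature(clean)), 50, tolerance = 0.05)

  noisy <- simulate_melt_curve(tm = 57, amplitude = 1, slope = 1.2,
                               noise_sd = 0.02, seed = 11)
  expect_equal(as.numeric(melting_temperature(noisy)), 57, tolerance = 0.2)

  flat <- melt_curve(seq(25, 95, 0.5), rep(1, 141))
  expect_error(melting_temperature(flat), class = "NoTransitionError")
})

test_that("delta Tm is signed and antisymmetric", {
  expect_equal(delta_tm(57.4, 50.0), 7.4)
  expect_equal(delta_tm(50, 50), 0)
  expect_equal(delta_tm(48, 50), -2)
  for (pair in list(c(55, 48), c(48, 55), c(62.3, 50.1))) {
    expect_equal(delta_tm(pair[1], pair[2]), -delta_tm(pair[2], pair[1]))
  }
})

test_that("velocity comes from the linear range of the trace", {
  line <- simulate_kinetic_trace(slope = -3, noise_sd = 0)
  v <- linear_range_velocity(line)
  expect_equal(as.numeric(v), 3)
  expect_equal(attr(v, "slope"), -3)

  piece <- simulate_kinetic_trace(slope = -3, duration = 100, n = 50,
                                  plateau_start = 60, noise_sd = 0)
  vp <- linear_range_velocity(piece)
  expect_equal(as.numeric(vp), 3, tolerance = 1e-8)
  expect_lte(attr(vp, "window")[2], 31)           # decay segment only

  flat <- simulate_kinetic_trace(slope = 0, noise_sd = 0)
  vf <- linear_range_velocity(flat)
  expect_equal(as.numeric(vf), 0)
  expect_true(attr(vf, "degenerate"))

  wiggly <- kinetic_trace(seq(0, 99, 1), 100 * sin(seq(0, 99, 1) / 5))
  expect_error(linear_range_velocity(wiggly), class = "NonLinearTraceError")
})

test_that("activity ratios express the activator/inhibitor switch", {
  expect_equal(normalized_activity(3, 3), 1)
  expect_equal(normalized_activity(6, 3), 2)     # activation
  expect_equal(normalized_activity(0.3, 3), 0.1) # inhibition
})

test_that("4PL fitting recovers IC50 and applies the technical floor", {
  clean <- simulate_dose_response(ic50 = 100, hill = 1, noise_sd = 0)
  fit <- fit_ic50(clean)
  expect_equal(fit$fitted_ic50, 100, tolerance = 0.01)
  expect_false(fit$censored)

  # IC50 below the enzyme-concentration floor is censored
  low <- simulate_dose_response(ic50 = 30, hill = 1, noise_sd = 0)
  cens <- fit_ic50(low, floor = 100)
  expect_true(cens$censored)
  expect_identical(cens$reported, "< 100 nM")
  expect_equal(cens$ic50, 100)

  flat <- dose_response(10^(1:6), rep(100, 6))
  expect_error(fit_ic50(flat), class = "FitError")
})

test_that("censoring triggers exactly when the fit crosses the floor", {
  for (true_ic50 in c(20, 50, 99, 101, 500, 5000)) {
    dr <- simulate_dose_response(ic50 = true_ic50, noise_sd = 0)
    fit <- fit_ic50(dr, floor = 100)
    expect_identical(fit$censored, fit$fitted_ic50 < 100, label = true_ic50)
  }
  # no floor, never censored
  fit <- fit_ic50(simulate_dose_response(ic50 = 5, noise_sd = 0))
  expect_false(fit$censored)
})

test_that("IC50 recovery is unbiased at 3% noise over Monte-Carlo seeds", {
  errs <- vapply(1:200, function(s) {
    dr <- simulate_dose_response(ic50 = 150, hill = 1, noise_sd = 3, seed = s)
    fit_ic50(dr)$fitted_ic50 / 150 - 1
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.02)     # unbiased within Monte-Carlo error
  expect_lt(mean(abs(errs)), 0.10)     # mean relative error within 10%
})

test_that("one-site ITC recovers the campaign-scale dissociation constant", {
  iso <- simulate_itc_isotherm(sites = data.frame(n = 1, kd_nm = 37, dh = -8),
                               noise_frac = 0)
  fit <- itc_fit(iso, "one_site")
  expect_equal(fit$sites$kd_nm, 37, tolerance = 0.05)
  expect_equal(fit$sites$n, 1, tolerance = 0.02)
  expect_equal(fit$sites$dh, -8, tolerance = 0.05)
})

test_that("two-site ITC resolves both constants on a biphasic isotherm", {
  truth <- data.frame(n = c(1, 1), kd_nm = c(100, 10000), dh = c(-8, -3))
  iso <- simulate_itc_isotherm(sites = truth, noise_frac = 0.001, seed = 4)
  fit <- itc_fit(iso, "two_site")
  expect_equal(fit$sites$kd_nm[1], 100, tolerance = 0.2)
  expect_equal(fit$sites$kd_nm[2], 10000, tolerance = 0.2)
  expect_false(fit$indistinguishable)

  expect_error(itc_fit(itc_isotherm(rep(0, 15), 2.5, 80, 400), "one_site"),
               class = "NoBindingSignalError")
})

test_that("two-site on monophasic data flags indistinguishable sites", {
  iso <- simulate_itc_isotherm(sites = data.frame(n = 1, kd_nm = 500, dh = -8),
                               noise_frac = 0)
  one <- itc_fit(iso, "one_site")
  two <- itc_fit(iso, "two_site")
  # nesting: the one-site residual cannot beat two sites by more than tol
  expect_lte(one$residual_norm, two$residual_norm + 1e-6)
  # either the CIs overlap or one site carries (numerically) all the signal
  expect_true(two$indistinguishable ||
                min(two$sites$n * abs(two$sites$dh)) <
                  0.05 * max(two$sites$n * abs(two$sites$dh)))
})
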