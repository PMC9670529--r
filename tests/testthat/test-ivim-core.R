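test_that("ivim_signal matches the bi-exponential model and its edge cases", {
  # b = 0 returns S0 exactly, for a spread of valid parameter sets
  set.seed(11)
  for (i in 1:20) {
    D <- runif(1, 1e-4, 3e-3)
    p <- ivim_params(S0 = runif(1, 10, 300), D = D,
                     f = runif(1, 0, 0.5), Dp = D * runif(1, 1, 30))
    expect_identical(ivim_signal(p, 0), p$S0)
  }

  # f = 0 collapses to the mono-exponential
  p0 <- ivim_params(100, 2.0e-3, 0, 2.0e-3)
  expect_equal(ivim_signal(p0, 500), 100 * exp(-1), tolerance = 1e-12)

  # frozen value computed independently: 90*exp(-0.36) + 10*exp(-4)
  p <- ivim_params(100, 1.8e-3, 0.10, 0.02)
  expect_equal(ivim_signal(p, 200), 62.974025735280136, tolerance = 1e-12)

  # monotone non-increasing in b, and above the high-b curve for f > 0
  b <- seq(0, 1000, by = 50)
  s <- ivim_signal(p, b)
  expect_true(all(diff(s) < 0))
  expect_true(all(s[-1] > high_b_signal(p, b[-1])))
  expect_true(all(s > 0))

  expect_error(ivim_signal(p, -1), "must be finite and >= 0")
  expect_error(ivim_params(100, -1e-3, 0.1, 0.02), "`D` must be")
  expect_error(ivim_params(100, 2e-3, 1.2, 0.02), "`f` must lie")
  expect_error(ivim_params(100, 2e-3, 0.1, 1e-3), "`Dp` must be")
})

test_that("high_b_signal is the perfusion-free mono-exponential", {
  expect_equal(high_b_signal(ivim_params(100, 2e-3, 0, 2e-3), 0), 100)
  # intercept is S0 * (1 - f)
  expect_equal(high_b_signal(ivim_params(100, 1e-3, 0.5, 1e-2), 0), 50)
  # frozen: 90 * exp(-1.8)
  expect_equal(high_b_signal(ivim_params(100, 1.8e-3, 0.10, 0.02), 1000),
               14.876899939942788, tolerance = 1e-12)
})

test_that("two-point ADC is the closed-form log-ratio", {
  expect_equal(fit_adc_two_point(100, 100), 0)
  expect_equal(fit_adc_two_point(100, 100 * exp(-1)), 1.0e-3, tolerance = 1e-12)
  expect_equal(fit_adc_two_point(200, 40), log(5) / 1000, tolerance = 1e-12)
  # undefined-voxel marker, not an exception
  expect_true(is.na(fit_adc_two_point(0, 40)))
  expect_identical(fit_adc_two_point(c(100, -5), c(50, 50)),
                   c(log(2) / 1000, NA_real_))
})

test_that("segmented fit is exact on noiseless mono-exponential curves", {
  sch <- default_bvalue_scheme()
  p <- ivim_params(100, 1.5e-3, 0, 1.5e-3)
  fit <- segmented_fit(signal_curve(sch, ivim_signal(p, sch$b_values)))
  expect_lt(abs(fit$D - 1.5e-3) / 1.5e-3, 1e-9)
  expect_lt(abs(fit$f), 1e-9)
  expect_identical(fit$S0, 100)

  # perfusion term truncated above the threshold: step 1 exact for f > 0 too
  p2 <- ivim_params(120, 2.2e-3, 0.15, 0.022)
  sig <- ivim_signal(p2, sch$b_values)
  hi <- sch$b_values >= 200
  sig[hi] <- high_b_signal(p2, sch$b_values[hi])
  fit2 <- segmented_fit(signal_curve(sch, sig))
  expect_lt(abs(fit2$D - p2$D) / p2$D, 1e-9)
  expect_lt(abs(fit2$f - p2$f) / p2$f, 1e-9)
})

test_that("segmented fit agrees with the brute-force grid-search oracle", {
  sch <- default_bvalue_scheme()
  b <- sch$b_values
  set.seed(42)
  for (i in 1:20) {
    D <- runif(1, 0.8e-3, 3.0e-3)
    p <- ivim_params(S0 = runif(1, 50, 250), D = D,
                     f = runif(1, 0.02, 0.35), Dp = D * runif(1, 5, 20))
    sig <- ivim_signal(p, b)
    fit <- segmented_fit(signal_curve(sch, sig))
    orc <- oracle_segmented_fit(sig, b)
    # within the refined grid resolution
    expect_equal(fit$D, orc$D, tolerance = 2e-3)
    expect_equal(fit$f, orc$f, tolerance = 2e-3)
    expect_equal(fit$Dp, orc$Dp, tolerance = 5e-3)
  }
})

test_that("segmented fit is scale invariant", {
  sch <- default_bvalue_scheme()
  set.seed(7)
  for (i in 1:10) {
    D <- runif(1, 1e-3, 3e-3)
    p <- ivim_params(100, D, runif(1, 0.02, 0.3), D * 10)
    sig <- ivim_signal(p, sch$b_values) * (1 + 0.02 * rnorm(length(sch)))
    sig <- pmax(sig, 1)
    c0 <- segmented_fit(signal_curve(sch, sig))
    for (scale in c(0.1, 7.3)) {
      c1 <- segmented_fit(signal_curve(sch, sig * scale))
      expect_equal(c1$D, c0$D, tolerance = 1e-12)
      expect_equal(c1$f, c0$f, tolerance = 1e-12)
      expect_equal(c1$Dp, c0$Dp, tolerance = 1e-6)
      expect_equal(c1$S0, c0$S0 * scale, tolerance = 1e-12)
    }
  }
})

test_that("bias of D and f shrinks monotonically as noise goes to zero", {
  sch <- default_bvalue_scheme()
  tt <- tissue_table("patients")
  p <- ivim_params(tt$S0[2], tt$D[2], tt$f[2], tt$Dp[2])  # synovium
  # reference: the noiseless segmented-fit estimate (the estimator's own
  # fixed point, so what remains at sigma -> 0 is exactly zero)
  ref <- segmented_fit(signal_curve(sch, ivim_signal(p, sch$b_values)))
  bias <- sapply(seq_along(c(10, 50, 250)), function(k) {
    snr <- c(10, 50, 250)[k]
    Y <- make_noisy_curves(p, sch, snr, n_rep = 300, seed = 100 + k)
    fits <- fit_curve_matrix(Y, sch)
    c(D = abs(mean(fits$D) - ref$D), f = abs(mean(fits$f) - ref$f))
  })
  expect_true(all(diff(bias["D", ]) < 0))
  expect_true(all(diff(bias["f", ]) < 0))
})

test_that("degenerate curves produce the fit-failure marker, not an error", {
  sch <- default_bvalue_scheme()
  sig <- ivim_signal(ivim_params(100, 2e-3, 0.1, 0.02), sch$b_values)
  sig[sch$b_values >= 300] <- 0          # only one positive high-b point
  fit <- segmented_fit(signal_curve(sch, sig))
  expect_match(fit$flags, "fit_failed")
  expect_true(is.na(fit$D) && is.na(fit$f))
})

test_that("fit configuration round-trips through JSON", {
  cfg <- fit_config(b_threshold = 300, Dp_max = 0.4, tol = 1e-10)
  js <- fit_config_to_json(cfg)
  cfg2 <- fit_config_from_json(js)
  expect_equal(unclass(cfg), unclass(cfg2))
  expect_error(fit_config(D_bounds = c(0, 1e-3)))
})
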