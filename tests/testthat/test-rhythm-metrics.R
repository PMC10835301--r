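test_that("phase and amplitude use the quadrant-aware arctangent", {
  ps <- instantaneous_phase_amplitude(c(1, 0, -1, 0), c(0, 1, 0, -1))
  expect_equal(ps$phase, c(0, pi / 2, pi, -pi / 2))
  expect_equal(ps$amplitude, rep(1, 4))
  expect_equal(ps$n_undefined, 0)

  # origin: phase undefined, counted
  ps0 <- instantaneous_phase_amplitude(c(0, 1), c(0, 0))
  expect_true(is.na(ps0$phase[1]))
  expect_equal(ps0$n_undefined, 1)
})

test_that("a noiseless on-cycle run has phase linear in time with slope 2*pi/tau", {
  p <- oscillator_params(sigma_x = 0, sigma_y = 0)
  g <- short_grid(5)
  sol <- integrate_ode(poincare_drift(p), c(p$A, 0), g)
  ph <- instantaneous_phase_amplitude(sol[, 2], sol[, 3],
                                      unwrap = TRUE)$unwrapped
  resid <- ph - 2 * pi * sol[, "time_h"] / p$tau
  expect_lt(max(abs(resid - resid[1])), 1e-3)
})

test_that("zero-crossing periods are exact on clean signals and error on flat ones", {
  t <- seq(0, 240, by = 0.01)
  zc <- period_zero_crossings(cos(2 * pi * t / 24), t)
  expect_equal(zc$period, 24, tolerance = 0.001 / 24)
  # crossing times are the descending zeros of cos: 6 h mod 24
  expect_equal(zc$crossings[1] %% 24, 6, tolerance = 1e-3)

  expect_error(period_zero_crossings(rep(1, 100), seq_len(100)), "no rhythm")
})

test_that("hysteresis suppresses noise-induced spurious crossings without biasing clean periods", {
  t <- seq(0, 480, by = 0.1)
  set.seed(4)
  noisy <- cos(2 * pi * t / 24) + rnorm(length(t), sd = 0.08)
  raw <- period_zero_crossings(noisy, t, hysteresis = 0)$period
  guarded <- period_zero_crossings(noisy, t)$period
  expect_lt(raw, 23)                     # jitter shortens the naive estimate
  expect_equal(guarded, 24, tolerance = 0.002)
})

test_that("the periodogram finds dominant and secondary periods and flags flat spectra", {
  t <- seq(0, 2400, by = 0.1)

  pure <- periodogram_dominant_period(sin(2 * pi * t / 24), t)
  expect_false(pure$arrhythmic)
  expect_equal(pure$period, 24, tolerance = 0.25 / 24)

  two <- periodogram_dominant_period(
    2 * sin(2 * pi * t / 23.6) + sin(2 * pi * t / 26.2), t)
  expect_equal(two$period, 23.6, tolerance = 0.01)
  expect_true(any(abs(two$peaks$period_h - 26.2) < 0.25))

  flat <- periodogram_dominant_period(rep(3, 500), seq(0, 49.9, by = 0.1))
  expect_true(flat$arrhythmic)
  expect_true(is.na(flat$period))
})

test_that("a single noisy oscillator at tau = 24.23 h peaks near 24.2 h over 100 days", {
  g <- sim_grid(dt = 0.01, t_end = 2400, transient = 0, record_stride = 10L)
  sim <- simulate_ensemble(ensemble_spec(n = 1, tau_sd = 0), g, seed = 8)
  pg <- periodogram_dominant_period(sim$x[1, ], sim$times, transient = 480)
  expect_equal(pg$period, 24.2, tolerance = 0.5 / 24.2)
})

test_that("autocorrelation distinguishes pure, noisy and unstructured signals", {
  t <- seq(0, 960, by = 0.1)
  pure <- autocorrelation(sin(2 * pi * t / 24), dt = 0.1)
  expect_equal(pure$acf[1], 1)
  expect_lt(abs(pure$decay_rate), 0.002)

  set.seed(5)
  wn <- autocorrelation(rnorm(5000), dt = 0.1)
  expect_lt(quantile(abs(wn$acf[-1]), 0.99), 3.5 / sqrt(5000))

  g <- sim_grid(dt = 0.01, t_end = 960, transient = 0, record_stride = 10L)
  sim <- simulate_ensemble(ensemble_spec(n = 1, tau_sd = 0), g, seed = 9)
  noisy <- autocorrelation(sim$x[1, ], dt = 0.1)
  expect_gt(noisy$decay_rate, 0)
})

test_that("the order parameter matches hand-computed phase sets and stays in [0, 1]", {
  expect_equal(order_parameter(rep(1.3, 7)), 1)
  expect_equal(order_parameter(2 * pi * (0:9) / 10), 0, tolerance = 1e-12)
  expect_equal(order_parameter(c(0, pi / 2)), sqrt(2) / 2)
  expect_equal(order_parameter(0.4), 1)  # single oscillator

  set.seed(6)
  m <- matrix(runif(50 * 20, -pi, pi), 50, 20)
  r0 <- order_parameter(m)
  expect_length(r0, 20)
  expect_true(all(r0 >= 0 & r0 <= 1))
  expect_error(order_parameter(NA_real_), "undefined")
})

test_that("circular standard deviation follows sqrt(-2 log Rbar) with its edge cases", {
  expect_equal(circular_std(rep(0.7, 5)), 0)
  expect_equal(circular_std(c(0, pi / 2)), sqrt(-2 * log(sqrt(2) / 2)))
  expect_equal(circular_std(c(0, pi / 2)), 0.8326, tolerance = 1e-4)
  expect_identical(circular_std(c(0, pi)), Inf)
  # rotation invariance
  ph <- c(0.1, 0.5, 2.8, -1.2)
  expect_equal(circular_std(ph), circular_std(ph + 1.234), tolerance = 1e-12)
  # hours on a 24 h cycle
  expect_equal(circular_std(c(0, pi / 2), hours = TRUE),
               0.8326 * 24 / (2 * pi), tolerance = 1e-4)
})

test_that("phase dispersion is zero for a noiseless identical ensemble and invariant to relabeling", {
  spec <- ensemble_spec(n = 8, tau_sd = 0,
                        shared = oscillator_params(sigma_x = 0, sigma_y = 0))
  sim <- simulate_ensemble(spec, short_grid(4), seed = 1)
  dc <- phase_dispersion_timecourse(list(sim))
  # identical trajectories: dispersion at the floating-point floor
  # (sqrt(-2 log(1 - eps)) ~ 1.5e-8), far below any physical dispersion
  expect_lt(max(dc$mean_curve), 1e-6)

  noisy <- simulate_ensemble(ensemble_spec(n = 8, tau_sd = 0),
                             short_grid(4), seed = 2)
  shuffled <- noisy
  perm <- c(3, 1, 2, 8, 5, 4, 7, 6)
  shuffled$x <- noisy$x[perm, ]
  shuffled$y <- noisy$y[perm, ]
  a <- phase_dispersion_timecourse(list(noisy))
  b <- phase_dispersion_timecourse(list(shuffled))
  expect_equal(a$mean_curve, b$mean_curve)
})

test_that("mean-field amplitude is half peak-to-trough, offset-invariant", {
  t <- seq(0, 480, by = 0.1)
  s <- 0.8 * sin(2 * pi * t / 24)
  expect_equal(mean_field_amplitude(s, t), 0.8, tolerance = 1e-3 / 0.8)
  expect_equal(mean_field_amplitude(s + 5, t), 0.8, tolerance = 1e-3 / 0.8)
  # fewer than 8 cycles: warns, still computes
  t2 <- seq(0, 24 * 5, by = 0.1)
  expect_warning(
    a <- mean_field_amplitude(sin(2 * pi * t2 / 24), t2),
    "cycles")
  expect_equal(a, 1, tolerance = 1e-3)
})

test_that("bootstrap Lowess reproduces clean trends and rejects degenerate input", {
  x <- seq(0, 1, length.out = 40)
  line <- bootstrap_lowess(x, 2 + 3 * x, seed = 1)
  expect_equal(line$mean, 2 + 3 * line$x, tolerance = 1e-6)
  expect_lt(max(line$upper - line$lower), 1e-6)

  flat <- bootstrap_lowess(x, rep(2, 40), seed = 1)
  expect_equal(flat$mean, rep(2, length(flat$x)), tolerance = 1e-9)

  set.seed(7)
  y <- x^2 + rnorm(40, sd = 0.01)
  sq <- bootstrap_lowess(x, y, seed = 2)
  expect_lt(max(abs(sq$mean - sq$x^2)), 0.05)

  expect_error(bootstrap_lowess(rep(1, 20), rnorm(20)), "degenerate")
  expect_error(bootstrap_lowess(1:5, 1:5), "at least 10")
})
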