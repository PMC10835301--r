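test_that("simulation grid validates its invariants and records exact times", {
  expect_error(sim_grid(dt = 0), "dt")
  expect_error(sim_grid(dt = -0.1), "dt")
  expect_error(sim_grid(dt = 0.1, t_end = 10, transient = 10), "transient")
  expect_error(sim_grid(dt = 0.1, t_end = 10, transient = 0,
                        record_stride = 0), "stride")

  g <- sim_grid(dt = 0.01, t_end = 5, transient = 1, record_stride = 7L)
  expect_equal(g$n_steps, 500L)
  out <- integrate_sde(function(t, s) 0, 1, g, sigma = 0)
  expect_identical(out[, "time_h"], seq(0L, 500L %/% 7L) * (7 * 0.01))
})

test_that("Euler-Maruyama with zero noise reduces to explicit Euler: matches the ODE solution at O(dt) and halves its error with dt", {
  rhs <- function(t, s) c(s[2], -s[1])  # harmonic oscillator, period 2*pi
  errs <- vapply(c(0.01, 0.005), function(dt) {
    g <- sim_grid(dt = dt, t_end = 20 * pi, transient = 0,
                  record_stride = round(0.1 / dt))
    em <- integrate_sde(rhs, c(1, 0), g, sigma = 0)
    ref <- integrate_ode(rhs, c(1, 0), g)
    max(abs(em[, 2] - ref[, 2]))
  }, numeric(1))
  # error is small but finite (first-order method over 10 cycles) ...
  expect_lt(errs[1], 0.5)
  expect_gt(errs[1], 1e-6)
  # ... and halving dt halves it (convergence order 1)
  expect_equal(errs[1] / errs[2], 2, tolerance = 0.15)
})

test_that("with zero drift the per-step noise increments have variance sigma^2 * dt", {
  g <- sim_grid(dt = 0.01, t_end = 1000, transient = 0, record_stride = 1L)
  out <- integrate_sde(function(t, s) 0, 0, g, sigma = 0.05, seed = 42)
  inc <- diff(out[, 2])
  n <- length(inc)  # 1e5 increments
  v <- var(inc)
  target <- 0.05^2 * 0.01
  # chi-square bound: at n = 1e5 the sample variance is within ~1.5% of the
  # truth with probability >> 0.999; assert the 5% band
  expect_equal(v, target, tolerance = 0.05)
  expect_gt(n, 99000)
})

test_that("the same seed reproduces the noise stream bit for bit", {
  g <- sim_grid(dt = 0.01, t_end = 10, transient = 0, record_stride = 5L)
  drift <- function(t, s) -0.1 * s
  a <- integrate_sde(drift, c(1, 2), g, sigma = c(0.05, 0.1), seed = 7)
  b <- integrate_sde(drift, c(1, 2), g, sigma = c(0.05, 0.1), seed = 7)
  expect_identical(a, b)
})

test_that("noise streams of distinct coordinates are uncorrelated", {
  g <- sim_grid(dt = 0.01, t_end = 1000, transient = 0, record_stride = 1L)
  out <- integrate_sde(function(t, s) c(0, 0), c(0, 0), g, sigma = 0.05,
                       seed = 99)
  i1 <- diff(out[, 2])
  i2 <- diff(out[, 3])
  expect_lt(abs(cor(i1, i2)), 0.02)
})

test_that("same seed and inputs give identical repeat runs of the compiled core", {
  spec <- ensemble_spec(n = 5, kc = 0.05)
  g <- sim_grid(dt = 0.02, t_end = 48, transient = 0, record_stride = 5L)
  a <- simulate_ensemble(spec, g, seed = 12)
  b <- simulate_ensemble(spec, g, seed = 12)
  expect_identical(a$x, b$x)
  expect_identical(a$y, b$y)
  expect_identical(a$tau_i, b$tau_i)
})

test_that("compiled ensemble core and the generic R integrator agree to numerical precision under one seed", {
  p <- oscillator_params()
  spec <- ensemble_spec(n = 4, tau_sd = 0.5, kc = 0.08)
  g <- sim_grid(dt = 0.02, t_end = 48, transient = 0, record_stride = 5L)

  sim <- simulate_ensemble(spec, g, seed = 31)

  # replay: same period draw, then the generic integrator with the same
  # drift and the same coordinate-ordered noise draws
  set.seed(31)
  tau_i <- rnorm(4, spec$tau_mean, spec$tau_sd)
  expect_identical(tau_i, sim$tau_i)
  params <- lapply(tau_i, function(tt) oscillator_params(tau = tt))
  ref <- integrate_sde(
    function(t, s) ensemble_drift(s, params, kc = spec$kc),
    c(rep(p$A, 4), rep(0, 4)), g,
    sigma = c(rep(p$sigma_x, 4), rep(p$sigma_y, 4))
  )
  # same update rule and noise draw order; the only difference is the
  # accumulation precision of the mean-field (long double in R's mean())
  expect_equal(unname(ref[, 2:5]), unname(t(sim$x)), tolerance = 1e-12)
  expect_equal(unname(ref[, 6:9]), unname(t(sim$y)), tolerance = 1e-12)
})

test_that("the deterministic solver reproduces the closed-form logistic radial relaxation", {
  # dr/dt = lambda * r * (A - r) has the logistic solution
  lam <- 0.05; A <- 1; r0 <- 0.5
  g <- sim_grid(dt = 0.1, t_end = 200, transient = 0, record_stride = 1L)
  sol <- integrate_ode(function(t, r) lam * r * (A - r), r0, g)
  tt <- sol[, "time_h"]
  closed <- A * r0 * exp(lam * A * tt) / (A + r0 * (exp(lam * A * tt) - 1))
  expect_equal(sol[, 2], closed, tolerance = 1e-6)

  # constant and exponential-decay sanity anchors
  flat <- integrate_ode(function(t, s) 0, 2.5, g)
  expect_true(all(flat[, 2] == 2.5))
  dec <- integrate_ode(function(t, s) -0.2 * s, 1, g)
  expect_equal(dec[, 2], exp(-0.2 * tt), tolerance = 1e-7)
})

test_that("non-finite states abort with a diagnostic step index", {
  g <- sim_grid(dt = 0.1, t_end = 100, transient = 0, record_stride = 1L)
  expect_error(integrate_sde(function(t, s) s^2, 1, g, sigma = 0),
               "non-finite state at integration step")
})
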