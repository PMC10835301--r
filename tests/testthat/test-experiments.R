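# Scaled-down experiment configurations: fewer oscillators, realizations and
# days than the headline runs, but the same dynamics and analyses.

test_that("heterogeneous ensembles desynchronize faster than identical ones", {
  g <- sim_grid(dt = 0.02, t_end = 360, transient = 0, record_stride = 5L)
  spec <- ensemble_spec(n = 20, tau_sd = 1.5)
  het <- run_desynchronization(identical = FALSE, n_realizations = 5,
                               spec = spec, grid = g, seed = 10)
  ident <- run_desynchronization(identical = TRUE, n_realizations = 5,
                                 spec = spec, grid = g, seed = 10)
  t_het <- het$times[which(het$mean_curve > 1)[1]]
  t_ident <- ident$times[which(ident$mean_curve > 1)[1]]
  expect_lt(t_het, t_ident)
})

test_that("a noiseless identical ensemble never disperses", {
  g <- sim_grid(dt = 0.02, t_end = 120, transient = 0, record_stride = 5L)
  spec <- ensemble_spec(n = 10, tau_sd = 0,
                        shared = oscillator_params(sigma_x = 0, sigma_y = 0))
  dc <- run_desynchronization(identical = TRUE, n_realizations = 2,
                              spec = spec, grid = g, seed = 1)
  expect_lt(max(dc$mean_curve), 1e-6)  # floating-point floor, see metrics tests
})

test_that("desynchronization experiments require an uncoupled, unforced spec", {
  expect_error(
    run_desynchronization(spec = ensemble_spec(kc = 0.1), grid = short_grid(1)),
    "kc = 0")
})

test_that("the entrainment test accepts the target, rejects other periods and flags beating", {
  t <- seq(0, 2400, by = 0.1)
  on <- entrainment_test(sin(2 * pi * t / 23.6), t)
  expect_true(on$entrained)
  expect_equal(on$period, 23.6, tolerance = 1e-3)

  off <- entrainment_test(sin(2 * pi * t / 26.2), t)
  expect_false(off$entrained)

  beat <- entrainment_test(sin(2 * pi * t / 23.6) + sin(2 * pi * t / 26.2), t)
  expect_false(beat$entrained)
  expect_true(beat$beating)

  silent <- entrainment_test(rep(0.5, 500), seq(0, 49.9, by = 0.1))
  expect_false(silent$entrained)
  expect_identical(silent$reason, "arrhythmic")
})

test_that("coupling increases order and mean-field amplitude across the sweep", {
  g <- sim_grid(dt = 0.02, t_end = 1440, transient = 360, record_stride = 5L)
  spec <- ensemble_spec(n = 50, tau_sd = 1.5)
  sw <- run_coupling_sweep(c(0, 0.05, 0.10, 0.15), n_realizations = 5,
                           spec = spec, grid = g, seed = 20)
  r0 <- aggregate(r0 ~ kc, data = sw$cells, FUN = mean)
  expect_true(all(diff(r0$r0) >= 0))

  amp <- aggregate(mf_amplitude ~ kc, data = sw$cells, FUN = mean)
  expect_gt(amp$mf_amplitude[amp$kc == 0.15], amp$mf_amplitude[amp$kc == 0])

  # sweep bookkeeping: one row per (kc, realization), seeded cells
  expect_equal(nrow(sw$cells), 20)
  expect_false(any(duplicated(sw$cells$seed)))
})

test_that("the minimal entraining TTFL input does not decrease with coupling strength", {
  g <- sim_grid(dt = 0.02, t_end = 1440, transient = 360, record_stride = 5L)
  gw <- simulate_goodwin(grid = sim_grid(dt = 0.05, t_end = 1440,
                                         transient = 360, record_stride = 1L))
  spec <- ensemble_spec(n = 50, tau_sd = 1.5)
  curve <- min_ttfl_for_entrainment(c(0.02, 0.10), c(0.10, 0.25),
                                    spec = spec, grid = g, drive = gw,
                                    n_realizations = 1, seed = 30)
  need <- ifelse(curve$censored, Inf, curve$min_kttfl)
  expect_true(all(diff(need) >= 0))
  # weak coupling entrains within the searched range
  expect_false(curve$censored[1])
  expect_lte(curve$min_kttfl[1], 0.25)
})

test_that("TTFL sweep reports per-strength periods, spectra and majority entrainment", {
  g <- sim_grid(dt = 0.02, t_end = 1440, transient = 360, record_stride = 5L)
  gw <- simulate_goodwin(grid = sim_grid(dt = 0.05, t_end = 1440,
                                         transient = 360, record_stride = 1L))
  spec <- ensemble_spec(n = 50, tau_sd = 1.5)
  sw <- run_ttfl_sweep(c(0, 0.25), kc = 0.05, spec = spec, grid = g,
                       drive = gw, seed = 40)
  expect_equal(nrow(sw$cells), 2)
  # unforced: free-running mean-field well above the TTFL period
  expect_gt(sw$cells$mf_period[sw$cells$k_ttfl == 0], 24.5)
  expect_false(sw$by_kttfl$entrained[sw$by_kttfl$k_ttfl == 0])
  # strong forcing: entrained at the TTFL period
  expect_true(sw$by_kttfl$entrained[sw$by_kttfl$k_ttfl == 0.25])
  expect_length(sw$spectra, 2)
  expect_true(all(c("period_h", "power_norm") %in% names(sw$spectra[[1]])))
})
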