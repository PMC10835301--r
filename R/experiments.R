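#' Desynchronization experiment
#'
#' Simulates `n_realizations` uncoupled, unforced ensembles and returns the
#' realization-averaged phase-dispersion curve with its fitted power-law
#' exponent. With `identical = TRUE` all oscillators share the mean period
#' (`tau_sd = 0`); otherwise periods are heterogeneous. Trajectories are
#' analysed and discarded one at a time so memory stays bounded.
#'
#' @param identical If `TRUE`, identical intrinsic periods; if `FALSE`,
#'   heterogeneous (the ensemble specification's `tau_sd`).
#' @param n_realizations Number of independent ensembles (default 50).
#' @param spec An [ensemble_spec()] with `kc = 0` and `k_ttfl = 0`.
#' @param grid A [sim_grid()].
#' @param seed Base seed; realization k uses `seed + k`.
#'
#' @return A [phase_dispersion_timecourse()]-style `dispersion_curve`.
#' @export
run_desynchronization <- function(identical = TRUE, n_realizations = 50L,
                                  spec = ensemble_spec(), grid = sim_grid(),
                                  seed = 1L) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (spec$kc != 0 || spec$k_ttfl != 0)
    stop("desynchronization experiment requires kc = 0 and k_ttfl = 0")
  spec$tau_sd <- if (identical) 0 else spec$tau_sd
  n_times <- grid$n_steps %/% grid$record_stride + 1L
  disp <- matrix(NA_real_, n_times, n_realizations)
  times <- recorded_times(grid)
  for (k in seq_len(n_realizations)) {
    sim <- simulate_ensemble(spec, grid, seed = seed + k)
    disp[, k] <- ensemble_circular_std(sim)
  }
  new_dispersion_curve(times, disp)
}

#' Coupling-strength sweep
#'
#' For every coupling strength on `kc_grid` and every realization:
#' time-averaged order parameter R0 (over the last 8 mean-field cycles),
#' per-oscillator zero-crossing periods (mean and SD across the ensemble),
#' mean-field dominant periodogram period and mean-field amplitude (last 8
#' cycles). With a `drive` and `k_ttfl > 0` the sweep also evaluates the
#' entrainment test per cell (the coupling-versus-entrainment experiment).
#'
#' @param kc_grid Numeric vector of coupling strengths.
#' @param n_realizations Realizations per grid value (default 5).
#' @param spec Template [ensemble_spec()] (its `kc` is overridden).
#' @param grid A [sim_grid()].
#' @param drive Optional TTFL drive (see [simulate_ensemble()]).
#' @param k_ttfl TTFL strength applied to every cell (default `spec$k_ttfl`).
#' @param target_period,tol Entrainment test parameters (see
#'   [entrainment_test()]).
#' @param seed Base seed; cell (i, k) uses `seed + 1000 * i + k`.
#'
#' @return Object of class `sweep_result`: `cells` (data.frame with one row
#'   per (kc, realization)), `periods` (list of per-oscillator period
#'   vectors), and the call parameters.
#' @export
run_coupling_sweep <- function(kc_grid, n_realizations = 5L,
                               spec = ensemble_spec(), grid = sim_grid(),
                               drive = NULL, k_ttfl = spec$k_ttfl,
                               target_period = 23.6, tol = 0.3, seed = 1L) {
  cells <- expand.grid(realization = seq_len(n_realizations), kc = kc_grid)
  cells <- cells[, c("kc", "realization")]
  cells$seed <- seed + 1000L * match(cells$kc, kc_grid) + cells$realization
  res <- vector("list", nrow(cells))
  periods <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    sp <- spec
    sp$kc <- cells$kc[j]
    sp$k_ttfl <- k_ttfl
    sim <- simulate_ensemble(sp, grid, drive = drive, seed = cells$seed[j])
    m <- ensemble_cell_metrics(sim, target_period = target_period, tol = tol)
    res[[j]] <- m$row
    periods[[j]] <- m$periods
  }
  cells <- cbind(cells, do.call(rbind, res))
  structure(
    list(cells = cells, periods = periods, kc_grid = kc_grid,
         k_ttfl = k_ttfl, n_realizations = n_realizations, seed = seed),
    class = "sweep_result"
  )
}

# summary metrics of one ensemble realization over the post-transient window
ensemble_cell_metrics <- function(sim, target_period = 23.6, tol = 0.3) {
  tr <- sim$grid$transient
  keep <- sim$times >= tr
  tt <- sim$times[keep]
  mf <- sim$mean_field[keep]

  ph <- atan2(sim$y[, keep, drop = FALSE], sim$x[, keep, drop = FALSE])
  r0_series <- order_parameter(ph)
  # time-average R0 over the last 8 mean-field cycles (fall back to the
  # whole window when the mean-field has no detectable rhythm)
  r0_win <- tryCatch({
    zc <- period_zero_crossings(mf, tt)
    tt >= tail(zc$crossings, 9L)[1L]
  }, error = function(e) rep(TRUE, length(tt)))
  r0 <- mean(r0_series[r0_win])

  per_i <- apply(sim$x[, keep, drop = FALSE], 1L, function(s)
    tryCatch(period_zero_crossings(s, tt)$period, error = function(e) NA_real_))
  pg <- periodogram_dominant_period(mf, tt)
  amp <- tryCatch(suppressWarnings(mean_field_amplitude(mf, tt)),
                  error = function(e) NA_real_)
  ent <- entrainment_test(mf, tt, target_period = target_period, tol = tol)
  list(
    row = data.frame(
      r0 = r0, mf_period = pg$period, mf_amplitude = amp,
      period_mean = mean(per_i, na.rm = TRUE),
      period_sd = sd(per_i, na.rm = TRUE),
      entrained = ent$entrained, arrhythmic = pg$arrhythmic
    ),
    periods = per_i
  )
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %d grid values x %d realizations (K_TTFL = %g)\n",
              length(x$kc_grid), x$n_realizations, x$k_ttfl))
  agg <- aggregate(cbind(r0, mf_period, mf_amplitude) ~ kc, data = x$cells,
                   FUN = mean)
  print(agg, row.names = FALSE)
  invisible(x)
}

#' Entrainment test on a mean-field signal
#'
#' The ensemble counts as entrained to the forcing period when the dominant
#' periodogram period of the mean-field lies within `tol` of
#' `target_period` AND no secondary spectral peak of at least half the
#' maximal power lies outside that tolerance (which would indicate beating:
#' co-existing ensemble and forcing frequencies).
#'
#' @param mean_field Numeric vector.
#' @param times Time stamps (h).
#' @param target_period Forcing period (h), default 23.6.
#' @param tol Tolerance (h), default 0.3 (above the spectral resolution of
#'   an 80-day window near 24 h).
#' @param transient Initial span (h) to discard.
#'
#' @return List: `entrained` (logical), `period`, `beating` (logical),
#'   `peaks`, `reason`.
#' @export
entrainment_test <- function(mean_field, times, target_period = 23.6,
                             tol = 0.3, transient = 0) {
  pg <- periodogram_dominant_period(mean_field, times, transient = transient)
  if (pg$arrhythmic)
    return(list(entrained = FALSE, period = NA_real_, beating = FALSE,
                peaks = pg$peaks, reason = "arrhythmic"))
  big <- pg$peaks[pg$peaks$power_norm >= 0.5, , drop = FALSE]
  off <- abs(big$period_h - target_period) > tol
  beating <- nrow(big) > 1L && any(off)
  if (abs(pg$period - target_period) > tol)
    return(list(entrained = FALSE, period = pg$period, beating = beating,
                peaks = pg$peaks, reason = "dominant period off target"))
  if (any(off))
    return(list(entrained = FALSE, period = pg$period, beating = TRUE,
                peaks = pg$peaks,
                reason = "secondary peak outside tolerance (beating)"))
  list(entrained = TRUE, period = pg$period, beating = FALSE,
       peaks = pg$peaks, reason = "entrained")
}

#' TTFL-strength sweep at fixed coupling
#'
#' For each TTFL input strength on `kttfl_grid`, simulates the ensemble at
#' coupling `kc`, computes the mean-field dominant period, the normalized
#' spectrum and the entrainment flag (majority vote over realizations).
#'
#' @param kttfl_grid Numeric vector of TTFL strengths.
#' @param kc Fixed coupling strength (default 0.05, a weakly coupled
#'   ensemble).
#' @param spec Template [ensemble_spec()].
#' @param grid A [sim_grid()].
#' @param drive TTFL drive (required; see [simulate_ensemble()]).
#' @param n_realizations Realizations per grid value (default 1).
#' @param target_period,tol Entrainment test parameters.
#' @param seed Base seed.
#'
#' @return List of class `ttfl_sweep`: `cells` data.frame (`k_ttfl`,
#'   `realization`, `seed`, `mf_period`, `entrained`, `beating`),
#'   `by_kttfl` majority-vote summary, `spectra` (one per cell).
#' @export
run_ttfl_sweep <- function(kttfl_grid, kc = 0.05, spec = ensemble_spec(),
                           grid = sim_grid(), drive, n_realizations = 1L,
                           target_period = 23.6, tol = 0.3, seed = 1L) {
  cells <- expand.grid(realization = seq_len(n_realizations),
                       k_ttfl = kttfl_grid)
  cells <- cells[, c("k_ttfl", "realization")]
  cells$seed <- seed + 1000L * match(cells$k_ttfl, kttfl_grid) +
    cells$realization
  spectra <- vector("list", nrow(cells))
  rows <- vector("list", nrow(cells))
  for (j in seq_len(nrow(cells))) {
    sp <- spec
    sp$kc <- kc
    sp$k_ttfl <- cells$k_ttfl[j]
    sim <- simulate_ensemble(sp, grid,
                             drive = if (sp$k_ttfl > 0) drive else NULL,
                             seed = cells$seed[j])
    keep <- sim$times >= grid$transient
    mf <- sim$mean_field[keep]
    tt <- sim$times[keep]
    pg <- periodogram_dominant_period(mf, tt)
    ent <- entrainment_test(mf, tt, target_period = target_period, tol = tol)
    rows[[j]] <- data.frame(mf_period = pg$period, entrained = ent$entrained,
                            beating = ent$beating)
    spectra[[j]] <- pg$spectrum
  }
  cells <- cbind(cells, do.call(rbind, rows))
  by_kttfl <- aggregate(entrained ~ k_ttfl, data = cells,
                        FUN = function(z) mean(z) > 0.5)
  structure(list(cells = cells, by_kttfl = by_kttfl, kc = kc,
                 spectra = spectra, seed = seed),
            class = "ttfl_sweep")
}

#' Minimal entraining TTFL input as a function of coupling strength
#'
#' For every coupling strength on `kc_grid`, searches `kttfl_grid` (in
#' increasing order) for the smallest TTFL input whose ensemble passes the
#' entrainment test by majority vote over `n_realizations` realizations.
#' Coupling strengths for which no grid value entrains are reported as
#' censored (above the search grid), not as errors.
#'
#' @param kc_grid Coupling strengths to scan.
#' @param kttfl_grid Candidate TTFL strengths (increasing).
#' @param spec Template [ensemble_spec()].
#' @param grid A [sim_grid()].
#' @param drive TTFL drive.
#' @param n_realizations Realizations per cell (default 3).
#' @param target_period,tol Entrainment test parameters.
#' @param seed Base seed.
#'
#' @return data.frame: `kc`, `min_kttfl` (`NA` when censored), `censored`.
#' @export
min_ttfl_for_entrainment <- function(kc_grid, kttfl_grid,
                                     spec = ensemble_spec(),
                                     grid = sim_grid(), drive,
                                     n_realizations = 3L,
                                     target_period = 23.6, tol = 0.3,
                                     seed = 1L) {
  kttfl_grid <- sort(kttfl_grid)
  out <- data.frame(kc = kc_grid, min_kttfl = NA_real_, censored = TRUE)
  for (i in seq_along(kc_grid)) {
    for (kt in kttfl_grid) {
      votes <- logical(n_realizations)
      for (k in seq_len(n_realizations)) {
        sp <- spec
        sp$kc <- kc_grid[i]
        sp$k_ttfl <- kt
        sim <- simulate_ensemble(
          sp, grid, drive = if (kt > 0) drive else NULL,
          seed = seed + 100000L * i + 100L * match(kt, kttfl_grid) + k)
        keep <- sim$times >= grid$transient
        votes[k] <- entrainment_test(sim$mean_field[keep], sim$times[keep],
                                     target_period = target_period,
                                     tol = tol)$entrained
      }
      if (mean(votes) > 0.5) {
        out$min_kttfl[i] <- kt
        out$censored[i] <- FALSE
        break
      }
    }
  }
  out
}
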