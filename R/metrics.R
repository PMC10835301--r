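#' Instantaneous phase and amplitude of oscillator trajectories
#'
#' Phase is the quadrant-aware two-argument arctangent `atan2(y, x)`,
#' wrapped to (-pi, pi]; amplitude is the radial coordinate
#' `sqrt(x^2 + y^2)`. Points at the origin have undefined phase and are
#' returned as `NA` (their count is reported so downstream circular
#' statistics can log exclusions).
#'
#' @param x,y Numeric vectors or `n x T` matrices (oscillators in rows).
#' @param unwrap If `TRUE`, also return the phase unwrapped along time
#'   (rows), for dispersion/diffusion analyses. Circular statistics always
#'   use the wrapped phase.
#'
#' @return List of class `phase_series`: `phase`, `amplitude`, optionally
#'   `unwrapped`, and `n_undefined`.
#' @examples
#' instantaneous_phase_amplitude(c(1, 0), c(0, 1))$phase  # 0, pi/2
#' @export
instantaneous_phase_amplitude <- function(x, y, unwrap = FALSE) {
  stopifnot(length(x) == length(y))
  amp <- sqrt(x^2 + y^2)
  phase <- atan2(y, x)
  undef <- amp == 0
  phase[undef] <- NA_real_
  # atan2(0, -0) corner cases aside, atan2 returns [-pi, pi]; map -pi -> pi
  phase[!is.na(phase) & phase <= -pi] <- pi
  out <- list(phase = phase, amplitude = amp,
              n_undefined = sum(undef))
  if (unwrap) {
    out$unwrapped <- if (is.matrix(phase)) {
      t(apply(phase, 1L, unwrap_phase))
    } else {
      unwrap_phase(phase)
    }
  }
  structure(out, class = "phase_series")
}

# remove 2*pi jumps so the phase is continuous along time
unwrap_phase <- function(phi) {
  if (anyNA(phi)) stop("cannot unwrap a phase series with undefined points")
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1L], d))
}

#' Period from zero crossings with negative slope
#'
#' Removes the series mean, locates downward (positive-to-negative) zero
#' crossings by linear interpolation between bracketing samples, and
#' reports the mean interval between consecutive crossings.
#'
#' On noisy signals, jitter around the zero line produces spurious
#' crossings that bias the mean interval low. A symmetric hysteresis band
#' (Schmitt trigger) guards against this: a downward crossing is accepted
#' only on a descent that runs from above `+hysteresis * sd(series)` to
#' below the negative of that threshold, and the detector re-arms only
#' above the upper edge. Any constant within-cycle offset of the accepted
#' crossing cancels in the crossing-to-crossing intervals. On noiseless
#' signals the band has no effect. The guard is sized for signals whose
#' noise is small or correlated relative to the sampling interval (as in
#' the stochastic trajectories produced here); series with heavy
#' uncorrelated sample-to-sample noise should be smoothed before period
#' estimation.
#'
#' @param series Numeric vector.
#' @param times Time stamps (h), same length.
#' @param transient Initial span (h) discarded before the analysis.
#' @param demean If `TRUE` (default) the mean of the analysed window is
#'   removed first.
#' @param hysteresis Re-arm threshold as a fraction of the series SD
#'   (default 0.3; 0 disables the guard).
#'
#' @return List: `period` (h), `periods` (individual intervals),
#'   `crossings` (crossing times, h).
#' @examples
#' t <- seq(0, 240, by = 0.01)
#' period_zero_crossings(cos(2 * pi * t / 24), t)$period  # ~24
#' @export
period_zero_crossings <- function(series, times, transient = 0,
                                  demean = TRUE, hysteresis = 0.3) {
  stopifnot(length(series) == length(times))
  keep <- times >= transient
  s <- series[keep]
  tt <- times[keep]
  if (demean) s <- s - mean(s)
  n <- length(s)
  if (n < 3L) stop("no rhythm detected: series too short")
  i <- which(s[-n] > 0 & s[-1L] <= 0)
  if (length(i) >= 2L && hysteresis > 0) {
    thr <- hysteresis * sd(s)
    typ <- integer(n)
    typ[s > thr] <- 1L
    typ[s < -thr] <- -1L
    ev <- which(typ != 0L)
    te <- typ[ev]
    # fire at the first below-band sample after an above-band sample
    fire <- which(te == -1L & c(0L, te[-length(te)]) == 1L)
    if (length(fire)) {
      arm_idx <- ev[fire - 1L]  # last above-band sample before each fire
      # first downward zero crossing at or after the arming sample
      pos <- findInterval(arm_idx - 1L, i) + 1L
      i <- unique(i[pos[pos <= length(i)]])
    } else {
      i <- integer(0)
    }
  }
  if (length(i) < 2L)
    stop("no rhythm detected: fewer than 2 negative-slope zero crossings")
  tc <- tt[i] - s[i] * (tt[i + 1L] - tt[i]) / (s[i + 1L] - s[i])
  per <- diff(tc)
  list(period = mean(per), periods = per, crossings = tc)
}

#' Dominant period from an FFT periodogram
#'
#' Periodogram of the mean-removed, transient-trimmed series, zero-padded
#' (>= 4x by default) for frequency resolution, with parabolic interpolation
#' around the maximal-power bin. All local peaks above `peak_frac` of the
#' maximum power are reported, which is how beating (co-existing
#' frequencies) is detected. A series whose maximal power is
#' indistinguishable from the spectral background (max < 20x the median
#' power, or zero variance) is flagged arrhythmic.
#'
#' @param series Numeric vector sampled at a constant interval.
#' @param times Time stamps (h).
#' @param transient Initial span (h) to discard.
#' @param pad_factor Zero-padding factor (>= 1; the padded length is the
#'   next power of two >= `pad_factor * n`).
#' @param peak_frac Report local peaks with power >= this fraction of the
#'   maximum.
#'
#' @return List: `period` (h, `NA` if arrhythmic), `arrhythmic` flag,
#'   `peaks` (data.frame `period_h`, `power_norm`, sorted by power), and
#'   `spectrum` (data.frame `period_h`, `power_norm` over the half
#'   spectrum).
#' @export
periodogram_dominant_period <- function(series, times, transient = 0,
                                        pad_factor = 4, peak_frac = 0.2) {
  stopifnot(length(series) == length(times))
  keep <- times >= transient
  s <- series[keep]
  tt <- times[keep]
  n <- length(s)
  if (n < 16L) stop("series too short for a periodogram")
  dt <- (tt[n] - tt[1L]) / (n - 1L)
  s <- s - mean(s)
  if (var(s) == 0)
    return(list(period = NA_real_, arrhythmic = TRUE,
                peaks = data.frame(period_h = numeric(0),
                                   power_norm = numeric(0)),
                spectrum = NULL))
  nfft <- 2^ceiling(log2(pad_factor * n))
  pw <- Mod(fft(c(s, numeric(nfft - n))))^2
  half <- 2:(nfft %/% 2)         # drop the zero frequency
  pw <- pw[half]
  freq <- (half - 1L) / (nfft * dt)
  imax <- which.max(pw)
  if (max(pw) < 20 * median(pw))
    return(list(period = NA_real_, arrhythmic = TRUE,
                peaks = data.frame(period_h = numeric(0),
                                   power_norm = numeric(0)),
                spectrum = data.frame(period_h = 1 / freq,
                                      power_norm = pw / max(pw))))
  f_dom <- parabolic_peak(freq, pw, imax)

  m <- length(pw)
  is_peak <- c(FALSE, pw[2:(m - 1)] > pw[1:(m - 2)] &
                 pw[2:(m - 1)] >= pw[3:m], FALSE)
  is_peak <- is_peak & pw >= peak_frac * max(pw)
  pk <- which(is_peak)
  peaks <- data.frame(
    period_h = vapply(pk, function(k) 1 / parabolic_peak(freq, pw, k),
                      numeric(1)),
    power_norm = pw[pk] / max(pw)
  )
  peaks <- peaks[order(-peaks$power_norm), , drop = FALSE]
  row.names(peaks) <- NULL

  list(period = 1 / f_dom, arrhythmic = FALSE, peaks = peaks,
       spectrum = data.frame(period_h = 1 / freq, power_norm = pw / max(pw)))
}

# refine a spectral peak by fitting a parabola through log-power at the
# peak bin and its two neighbours
parabolic_peak <- function(freq, pw, i) {
  if (i <= 1L || i >= length(pw)) return(freq[i])
  y <- log(pw[(i - 1L):(i + 1L)] + .Machine$double.xmin)
  denom <- y[1L] - 2 * y[2L] + y[3L]
  if (denom >= 0) return(freq[i])
  delta <- 0.5 * (y[1L] - y[3L]) / denom
  freq[i] + delta * (freq[i + 1L] - freq[i])
}

#' Normalized autocorrelation function with envelope decay rate
#'
#' ACF of the (mean-removed) series, normalized to 1 at lag zero. The
#' envelope decay rate is estimated by a log-linear fit to the positive
#' cycle maxima of the ACF: a noiseless periodic signal gives a rate near
#' zero, a noisy self-sustained oscillator an exponentially decaying
#' cosine (positive rate).
#'
#' @param series Numeric vector sampled at constant interval.
#' @param dt Sampling interval (h).
#' @param max_lag_h Largest lag (h); default one third of the span.
#'
#' @return List: `lags_h`, `acf`, `decay_rate` (1/h, `NA` if fewer than two
#'   usable envelope maxima).
#' @export
autocorrelation <- function(series, dt, max_lag_h = NULL) {
  n <- length(series)
  if (is.null(max_lag_h)) max_lag_h <- n * dt / 3
  lag_max <- min(n - 1L, round(max_lag_h / dt))
  a <- acf(series, lag.max = lag_max, plot = FALSE, demean = TRUE)$acf[, 1, 1]
  lags <- (seq_along(a) - 1L) * dt

  # envelope: local maxima of the ACF with positive value, excluding lag 0
  m <- length(a)
  pk <- which(c(FALSE, a[2:(m - 1)] > a[1:(m - 2)] &
                  a[2:(m - 1)] >= a[3:m], FALSE) & a > 0.02)
  decay <- NA_real_
  if (length(pk) >= 2L) {
    fit <- lm(log(a[pk]) ~ lags[pk])
    decay <- -unname(coef(fit)[2L])
  }
  list(lags_h = lags, acf = a, decay_rate = decay)
}

#' Kuramoto order parameter (synchronization index)
#'
#' Modulus of the mean unit phasor,
#' \eqn{R_0 = |N^{-1} \sum_j e^{i\phi_j}|}: 0 for an incoherent ensemble,
#' 1 for identical phases. Undefined phases (`NA`) are excluded.
#'
#' @param phases Numeric vector of phases (radians) for one time point, or
#'   an `n x T` matrix (oscillators in rows), in which case a length-`T`
#'   series is returned.
#'
#' @return Scalar or vector of R0 values in [0, 1].
#' @examples
#' order_parameter(c(0, pi / 2))  # sqrt(2)/2
#' @export
order_parameter <- function(phases) {
  if (is.matrix(phases)) {
    cc <- colMeans(cos(phases), na.rm = TRUE)
    ss <- colMeans(sin(phases), na.rm = TRUE)
    if (all(is.nan(cc))) stop("all phases undefined")
    return(sqrt(cc^2 + ss^2))
  }
  ph <- phases[!is.na(phases)]
  if (length(ph) == 0L) stop("all phases undefined")
  sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
}

#' Circular standard deviation of phases
#'
#' \eqn{\sqrt{-2 \ln \bar R}}, where \eqn{\bar R} is the mean resultant
#' length of the unit phasors. For phases spread so that \eqn{\bar R = 0}
#' (e.g. an antipodal pair) the result is `Inf`.
#'
#' @param phases Numeric vector of phases (radians); `NA`s are excluded.
#' @param hours If `TRUE`, rescale radians to hours on a 24 h cycle
#'   (factor 24 / 2pi).
#'
#' @return Nonnegative scalar (radians, or hours if `hours = TRUE`).
#' @examples
#' circular_std(c(0, pi / 2))  # ~0.8326 rad
#' @export
circular_std <- function(phases, hours = FALSE) {
  ph <- phases[!is.na(phases)]
  if (length(ph) < 2L) stop("need at least 2 defined phases")
  rbar <- sqrt(mean(cos(ph))^2 + mean(sin(ph))^2)
  out <- if (rbar < 1e-12) Inf else sqrt(-2 * log(min(rbar, 1)))
  if (hours) out <- out * 24 / (2 * pi)
  out
}

# circular std across oscillators at every recorded time of one simulation
ensemble_circular_std <- function(sim) {
  ph <- atan2(sim$y, sim$x)
  cc <- colMeans(cos(ph))
  ss <- colMeans(sin(ph))
  rbar <- pmin(sqrt(cc^2 + ss^2), 1)
  ifelse(rbar < 1e-12, Inf, sqrt(-2 * log(rbar)))
}

#' Phase-dispersion time course across realizations
#'
#' For each realization, the circular standard deviation of the ensemble
#' phases at every recorded time; the dispersion curve is the mean across
#' realizations. A power-law exponent is fitted by log-log linear
#' regression over the pre-saturation window (from `fit_start` until the
#' mean dispersion first exceeds `saturation`); pure phase diffusion gives
#' an exponent of 0.5 (square-root-of-time growth).
#'
#' @param realizations List of `redox_ensemble_sim` objects sharing a grid.
#' @param fit_start Start (h) of the exponent fit window (default 12 h).
#' @param saturation Dispersion level (radians) ending the fit window
#'   (default 1.5 rad).
#'
#' @return Object of class `dispersion_curve`: `times`, `per_realization`
#'   (times x realizations matrix), `mean_curve`, `exponent` (`NA` with
#'   `saturated_from_start = TRUE` if the curve starts beyond saturation),
#'   and the fit window.
#' @export
phase_dispersion_timecourse <- function(realizations, fit_start = 12,
                                        saturation = 1.5) {
  stopifnot(length(realizations) >= 1L)
  times <- realizations[[1L]]$times
  for (r in realizations)
    if (!identical(length(r$times), length(times)) ||
        max(abs(r$times - times)) > 1e-9)
      stop("all realizations must share the same time grid")
  disp <- vapply(realizations, ensemble_circular_std,
                 numeric(length(times)))
  new_dispersion_curve(times, disp, fit_start, saturation)
}

new_dispersion_curve <- function(times, disp, fit_start = 12,
                                 saturation = 1.5) {
  mean_curve <- rowMeans(disp)
  over <- which(mean_curve > saturation & times > fit_start)
  fit_end <- if (length(over)) times[over[1L]] else max(times)
  win <- times >= fit_start & times <= fit_end & mean_curve > 0 &
    is.finite(mean_curve)
  exponent <- NA_real_
  saturated <- FALSE
  if (sum(win) >= 5L && fit_end > fit_start) {
    fit <- lm(log(mean_curve[win]) ~ log(times[win]))
    exponent <- unname(coef(fit)[2L])
  } else {
    saturated <- TRUE
  }
  structure(
    list(times = times, per_realization = disp, mean_curve = mean_curve,
         exponent = exponent, saturated_from_start = saturated,
         fit_window = c(fit_start, fit_end)),
    class = "dispersion_curve"
  )
}

#' @export
print.dispersion_curve <- function(x, ...) {
  cat(sprintf(
    "<dispersion_curve> %d realizations; power-law exponent %s (fit %g-%g h)\n",
    ncol(x$per_realization),
    if (is.na(x$exponent)) "NA" else sprintf("%.3f", x$exponent),
    x$fit_window[1L], x$fit_window[2L]))
  invisible(x)
}

#' @export
plot.dispersion_curve <- function(x, hours = TRUE, ...) {
  f <- if (hours) 24 / (2 * pi) else 1
  matplot(x$times / 24, x$per_realization * f, type = "l", lty = 1,
          col = grDevices::adjustcolor("grey60", 0.4),
          xlab = "time (days)",
          ylab = if (hours) "phase dispersion (h)" else
            "phase dispersion (rad)", ...)
  lines(x$times / 24, x$mean_curve * f, lwd = 2)
  invisible(x)
}

#' Mean-field amplitude over the last cycles of a run
#'
#' Half the peak-to-trough distance per cycle, averaged over the last
#' `n_cycles` cycles. Cycles are delimited by negative-slope zero
#' crossings of the mean-removed signal; within each cycle the amplitude is
#' `(max - min) / 2` of the raw signal, so a constant offset does not
#' change the result.
#'
#' @param mean_field Numeric vector.
#' @param times Time stamps (h).
#' @param n_cycles Number of trailing cycles to average (default 8). If
#'   fewer are present the available ones are used with a warning.
#'
#' @return Scalar amplitude (signal units).
#' @export
mean_field_amplitude <- function(mean_field, times, n_cycles = 8L) {
  zc <- period_zero_crossings(mean_field, times)
  cross <- zc$crossings
  n_avail <- length(cross) - 1L
  if (n_avail < n_cycles) {
    warning(sprintf("only %d full cycles available (%d requested)",
                    n_avail, n_cycles))
    n_cycles <- n_avail
  }
  cross <- tail(cross, n_cycles + 1L)
  amps <- vapply(seq_len(n_cycles), function(k) {
    w <- times >= cross[k] & times <= cross[k + 1L]
    (max(mean_field[w]) - min(mean_field[w])) / 2
  }, numeric(1))
  mean(amps)
}

#' Bootstrap Lowess summary of a scatter
#'
#' Repeats `n_boot` times: draw `frac_points` of the points without
#' replacement, fit a Lowess smoother, evaluate it on a common grid.
#' Returns the pointwise mean curve and a central confidence band — the
#' summary used for parameter-sweep scatters (e.g. R0 versus coupling
#' strength).
#'
#' @param x,y Numeric vectors (>= 10 points, `x` not all equal).
#' @param n_boot Number of bootstrap iterations (default 100).
#' @param frac_points Fraction of points per iteration (default 0.5).
#' @param span Lowess span, as a fraction of the subsample (default 0.4).
#' @param grid_n Number of evaluation points.
#' @param conf Width of the central confidence band (default 0.95).
#' @param seed Optional integer seed.
#'
#' @return List: `x` (grid), `mean`, `lower`, `upper`, `boot`
#'   (grid x n_boot matrix).
#' @export
bootstrap_lowess <- function(x, y, n_boot = 100L, frac_points = 0.5,
                             span = 0.4, grid_n = 50L, conf = 0.95,
                             seed = NULL) {
  stopifnot(length(x) == length(y))
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10L) stop("need at least 10 points")
  if (diff(range(x)) == 0) stop("degenerate x: all values equal")
  if (!is.null(seed)) set.seed(seed)
  gx <- seq(min(x), max(x), length.out = grid_n)
  n <- length(x)
  m <- max(4L, floor(frac_points * n))
  boot <- vapply(seq_len(n_boot), function(b) {
    idx <- sample.int(n, m)
    # iter = 0: plain local regression. The robustness iterations degenerate
    # when residuals vanish (zero MAD), and sweep scatters have no outliers.
    sm <- lowess(x[idx], y[idx], f = span, iter = 0)
    interp_linear_extrap(sm$x, sm$y, gx)
  }, numeric(grid_n))
  boot <- matrix(boot, nrow = grid_n)
  alpha <- (1 - conf) / 2
  list(x = gx,
       mean = rowMeans(boot),
       lower = apply(boot, 1L, quantile, probs = alpha),
       upper = apply(boot, 1L, quantile, probs = 1 - alpha),
       boot = boot)
}

# linear interpolation inside the fitted range, linear extrapolation from
# the end segments outside it (a subsample rarely spans the full x range;
# clamping would flatten every curve at the grid edges)
interp_linear_extrap <- function(sx, sy, gx) {
  out <- approx(sx, sy, xout = gx, rule = 2, ties = mean)$y
  k <- length(sx)
  if (k >= 2L) {
    lo <- gx < sx[1L]
    if (any(lo)) {
      s <- (sy[2L] - sy[1L]) / (sx[2L] - sx[1L])
      out[lo] <- sy[1L] + s * (gx[lo] - sx[1L])
    }
    hi <- gx > sx[k]
    if (any(hi)) {
      s <- (sy[k] - sy[k - 1L]) / (sx[k] - sx[k - 1L])
      out[hi] <- sy[k] + s * (gx[hi] - sx[k])
    }
  }
  out
}
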