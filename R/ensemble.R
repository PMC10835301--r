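#' Parameters of a single Poincare oscillator with twist
#'
#' The planar limit-cycle oscillator used for a single mitochondrial redox
#' (cytosolic H2O2) rhythm. In Cartesian coordinates, with
#' \eqn{r = \sqrt{x^2 + y^2}}:
#' \deqn{dx = \lambda x (A - r)\,dt - y\,[2\pi/\tau + \epsilon (A - r)]\,dt
#'   + \sigma_x dW_1,}
#' \deqn{dy = \lambda y (A - r)\,dt + x\,[2\pi/\tau + \epsilon (A - r)]\,dt
#'   + \sigma_y dW_2.}
#' `A` is the limit-cycle amplitude, `lam` the amplitude relaxation rate
#' (how fast radial perturbations decay; "rigid" oscillators have high
#' `lam`, "plastic" ones low), `eps` the twist (amplitude dependence of the
#' instantaneous frequency, producing period-amplitude correlations), `tau`
#' the intrinsic period and `sigma_x`, `sigma_y` the white-noise intensities
#' in the velocity field.
#'
#' @param A Limit-cycle amplitude (dimensionless), > 0.
#' @param lam Amplitude relaxation rate (1/h), >= 0.
#' @param eps Twist (1/h).
#' @param tau Intrinsic period (h), > 0.
#' @param sigma_x,sigma_y Noise intensities (signal / sqrt(h)), >= 0.
#'
#' @return An object of class `oscillator_params`.
#' @export
oscillator_params <- function(A = 1, lam = 0.05, eps = 0.05, tau = 24.23,
                              sigma_x = 0.05, sigma_y = 0.05) {
  stopifnot(is.numeric(A), A > 0, is.numeric(lam), lam >= 0,
            is.numeric(eps), is.numeric(tau), tau > 0,
            is.numeric(sigma_x), sigma_x >= 0,
            is.numeric(sigma_y), sigma_y >= 0)
  structure(list(A = A, lam = lam, eps = eps, tau = tau,
                 sigma_x = sigma_x, sigma_y = sigma_y),
            class = "oscillator_params")
}

#' @export
print.oscillator_params <- function(x, ...) {
  cat(sprintf(
    "<oscillator_params> A = %g, lambda = %g /h, twist = %g /h, tau = %g h, sigma = (%g, %g)\n",
    x$A, x$lam, x$eps, x$tau, x$sigma_x, x$sigma_y))
  invisible(x)
}

#' Specification of an oscillator ensemble
#'
#' Describes a population of `n` Poincare oscillators sharing all parameters
#' except the intrinsic period, which is drawn per oscillator from
#' Normal(`tau_mean`, `tau_sd`). `kc` is the strength of all-to-all
#' mean-field coupling (through the population average of the x
#' coordinates, modelling fast-diffusing cytosolic H2O2); `k_ttfl` the
#' strength of forcing by the normalized TTFL drive (applied to the y
#' coordinates).
#'
#' @param n Number of oscillators (default 100).
#' @param tau_mean,tau_sd Mean and SD (h) of the intrinsic-period
#'   distribution; defaults 24.23 h and 1.5 h.
#' @param shared [oscillator_params()] template shared by all oscillators
#'   (its `tau` is ignored; periods come from the draw).
#' @param kc Mean-field coupling strength (>= 0, default 0).
#' @param k_ttfl TTFL forcing strength (>= 0, default 0).
#' @param seed Integer seed for the realization (period draw plus noise).
#'
#' @return An object of class `ensemble_spec`.
#' @export
ensemble_spec <- function(n = 100L, tau_mean = 24.23, tau_sd = 1.5,
                          shared = oscillator_params(), kc = 0, k_ttfl = 0,
                          seed = NULL) {
  n <- as.integer(n)
  stopifnot(!is.na(n), n >= 1L, is.numeric(tau_mean), tau_mean > 0,
            is.numeric(tau_sd), tau_sd >= 0,
            inherits(shared, "oscillator_params"),
            is.numeric(kc), kc >= 0, is.numeric(k_ttfl), k_ttfl >= 0)
  structure(list(n = n, tau_mean = tau_mean, tau_sd = tau_sd,
                 shared = shared, kc = kc, k_ttfl = k_ttfl, seed = seed),
            class = "ensemble_spec")
}

#' @export
print.ensemble_spec <- function(x, ...) {
  cat(sprintf(
    "<ensemble_spec> n = %d, tau ~ N(%g, %g) h, Kc = %g, K_TTFL = %g%s\n",
    x$n, x$tau_mean, x$tau_sd, x$kc, x$k_ttfl,
    if (is.null(x$seed)) "" else sprintf(", seed = %d", x$seed)))
  print(x$shared)
  invisible(x)
}

#' Draw the oscillators of an ensemble
#'
#' Draws `n` intrinsic periods i.i.d. from Normal(`tau_mean`, `tau_sd`);
#' draws <= 1 h are redrawn (a guard for pathological specifications; at the
#' default 24.23 +/- 1.5 h this is never triggered in practice). All other
#' parameters are copied from the shared template.
#'
#' @param spec An [ensemble_spec()].
#' @param seed Optional integer seed; defaults to `spec$seed`. If `NULL`,
#'   the current RNG state is used.
#'
#' @return List of `n` [oscillator_params()] objects, with the drawn periods
#'   in attribute `"tau_i"`.
#' @export
make_ensemble <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "ensemble_spec"))
  if (!is.null(seed)) set.seed(seed)
  tau_i <- draw_periods(spec$n, spec$tau_mean, spec$tau_sd)
  params <- lapply(tau_i, function(tt) {
    p <- spec$shared
    p$tau <- tt
    p
  })
  attr(params, "tau_i") <- tau_i
  params
}

draw_periods <- function(n, tau_mean, tau_sd) {
  tau <- rnorm(n, tau_mean, tau_sd)
  for (guard in 1:100) {
    bad <- tau <= 1
    if (!any(bad)) break
    tau[bad] <- rnorm(sum(bad), tau_mean, tau_sd)
  }
  if (any(tau <= 1))
    stop("could not draw periods > 1 h; check tau_mean/tau_sd")
  tau
}

#' Drift field of the coupled ensemble
#'
#' Deterministic part of the ensemble dynamics for a concatenated state
#' `c(x_1..x_N, y_1..y_N)`. The mean-field coupling term `kc * M` (with
#' `M = mean(x)`) enters only the x equations; the TTFL forcing term enters
#' only the y equations.
#'
#' Used by tests and by the generic [integrate_sde()] route; the production
#' simulator evaluates the identical field in compiled code.
#'
#' @param state Numeric vector `c(x, y)` of length `2 * N`.
#' @param params List of `N` [oscillator_params()] (e.g. from
#'   [make_ensemble()]); `A`, `lam`, `eps` are taken from the first element
#'   (shared across the ensemble), periods per oscillator.
#' @param kc Mean-field coupling strength.
#' @param forcing Scalar external forcing at the current time, already
#'   scaled by the TTFL strength: `k_ttfl * drive(t)` (0 when unforced).
#'
#' @return Derivative vector of length `2 * N`.
#' @export
ensemble_drift <- function(state, params, kc = 0, forcing = 0) {
  N <- length(params)
  stopifnot(length(state) == 2L * N)
  x <- state[seq_len(N)]
  y <- state[N + seq_len(N)]
  p1 <- params[[1L]]
  tau <- vapply(params, `[[`, numeric(1), "tau")
  r <- sqrt(x^2 + y^2)
  rel <- p1$A - r
  omega <- 2 * pi / tau + p1$eps * rel
  M <- mean(x)
  dx <- p1$lam * x * rel - y * omega + kc * M
  dy <- p1$lam * y * rel + x * omega + forcing
  c(dx, dy)
}

#' Simulate a coupled ensemble of stochastic redox oscillators
#'
#' Integrates the coupled ensemble by Euler-Maruyama (compiled core). Every
#' oscillator starts on the limit cycle at `(x, y) = (A, 0)`, i.e. with a
#' common phase. When `spec$k_ttfl > 0` a TTFL drive must be supplied; it is
#' linearly interpolated onto the integration steps.
#'
#' @param spec An [ensemble_spec()].
#' @param grid A [sim_grid()].
#' @param drive TTFL forcing: a [simulate_goodwin()] result, or a list with
#'   elements `times` and `drive` (normalized drive, mean ~ 0). Required
#'   when `spec$k_ttfl > 0`, ignored otherwise.
#' @param seed Integer seed (defaults to `spec$seed`); seeds both the period
#'   draw and the noise stream of this realization.
#'
#' @return Object of class `redox_ensemble_sim` with elements `times`
#'   (recorded times, h), `x` and `y` (`n` x `T` matrices), `tau_i` (drawn
#'   periods), `mean_field` (`colMeans(x)`), plus `spec`, `grid`, `seed`.
#' @examples
#' spec <- ensemble_spec(n = 10, seed = 1)
#' g <- sim_grid(dt = 0.05, t_end = 120, transient = 0, record_stride = 2)
#' sim <- simulate_ensemble(spec, g)
#' @export
simulate_ensemble <- function(spec, grid, drive = NULL, seed = spec$seed) {
  stopifnot(inherits(spec, "ensemble_spec"), is_sim_grid(grid))
  p <- spec$shared

  drive_steps <- numeric(0)
  if (spec$k_ttfl > 0) {
    if (is.null(drive))
      stop("`drive` must be supplied when `k_ttfl > 0`")
    drive_steps <- drive_at_steps(drive, grid)
  }

  if (!is.null(seed)) set.seed(seed)
  tau_i <- draw_periods(spec$n, spec$tau_mean, spec$tau_sd)

  raw <- poincare_em_cpp(
    x0 = rep(p$A, spec$n), y0 = rep(0, spec$n), tau = tau_i,
    A = p$A, lambda = p$lam, eps = p$eps,
    sigma_x = p$sigma_x, sigma_y = p$sigma_y,
    Kc = spec$kc, Kttfl = spec$k_ttfl, drive = drive_steps,
    dt = grid$dt, nsteps = grid$n_steps, stride = grid$record_stride
  )

  structure(
    list(times = raw$times, x = raw$x, y = raw$y, tau_i = tau_i,
         mean_field = colMeans(raw$x), spec = spec, grid = grid,
         seed = seed),
    class = "redox_ensemble_sim"
  )
}

# Forcing value at the start of each integration step (linear interpolation;
# the drive is treated as an exogenous signal, not a co-integrated state).
drive_at_steps <- function(drive, grid) {
  if (inherits(drive, "goodwin_sim")) {
    if (is.null(drive$drive))
      stop("Goodwin run has no drive (no detectable cycles); cannot force")
    dt_times <- drive$times
    dv <- drive$drive
  } else if (is.list(drive) && !is.null(drive$times) && !is.null(drive$drive)) {
    dt_times <- drive$times
    dv <- drive$drive
  } else {
    stop("`drive` must be a goodwin_sim or a list(times, drive)")
  }
  step_t <- (seq_len(grid$n_steps) - 1L) * grid$dt
  if (max(dt_times) < max(step_t) || min(dt_times) > 0)
    stop("drive series does not cover the simulation time span")
  approx(dt_times, dv, xout = step_t, rule = 2)$y
}

#' @export
print.redox_ensemble_sim <- function(x, ...) {
  cat(sprintf(
    "<redox_ensemble_sim> %d oscillators, %d recorded times over %g h\n",
    nrow(x$x), length(x$times), max(x$times)))
  cat(sprintf("  Kc = %g, K_TTFL = %g, tau range %.2f-%.2f h\n",
              x$spec$kc, x$spec$k_ttfl, min(x$tau_i), max(x$tau_i)))
  invisible(x)
}

#' @export
summary.redox_ensemble_sim <- function(object, ...) {
  tr <- object$grid$transient
  keep <- object$times >= tr
  ph <- instantaneous_phase_amplitude(object$x[, keep, drop = FALSE],
                                      object$y[, keep, drop = FALSE])
  r0 <- order_parameter(ph$phase)
  mf <- object$mean_field[keep]
  tt <- object$times[keep]
  per <- tryCatch(periodogram_dominant_period(mf, tt)$period,
                  error = function(e) NA_real_)
  out <- list(
    n = nrow(object$x), kc = object$spec$kc, k_ttfl = object$spec$k_ttfl,
    r0_mean = mean(r0), mean_field_period = per,
    mean_field_amplitude = tryCatch(mean_field_amplitude(mf, tt),
                                    error = function(e) NA_real_)
  )
  class(out) <- "summary.redox_ensemble_sim"
  out
}

#' @export
print.summary.redox_ensemble_sim <- function(x, ...) {
  cat(sprintf("Ensemble of %d oscillators (Kc = %g, K_TTFL = %g)\n",
              x$n, x$kc, x$k_ttfl))
  cat(sprintf("  time-averaged order parameter R0: %.3f\n", x$r0_mean))
  cat(sprintf("  mean-field dominant period: %.2f h\n", x$mean_field_period))
  cat(sprintf("  mean-field amplitude (last 8 cycles): %.3f\n",
              x$mean_field_amplitude))
  invisible(x)
}

#' @export
plot.redox_ensemble_sim <- function(x, n_show = 5L, ...) {
  keep <- x$times >= x$grid$transient
  tt <- x$times[keep]
  idx <- seq_len(min(n_show, nrow(x$x)))
  matplot(tt / 24, t(x$x[idx, keep, drop = FALSE]), type = "l", lty = 1,
          col = grDevices::adjustcolor("grey40", 0.5),
          xlab = "time (days)", ylab = "x", ...)
  lines(tt / 24, x$mean_field[keep], col = "black", lwd = 2)
  legend("topright", legend = c("oscillators", "mean-field"),
         col = c("grey40", "black"), lwd = c(1, 2), bty = "n")
  invisible(x)
}
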