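#' Euler-Maruyama integration of a stochastic differential equation system
#'
#' Generic fixed-step Euler-Maruyama solver. At every step the state is
#' updated as
#' \deqn{s \leftarrow s + f(t, s)\,dt + \sigma \sqrt{dt}\,\xi,}
#' with \eqn{\xi} a vector of independent standard normal draws (one per
#' coordinate per step, drawn in coordinate order from R's RNG). With all
#' `sigma = 0` this reduces to the explicit Euler method.
#'
#' This is the reference implementation; the Poincare-ensemble simulator
#' ([simulate_ensemble()]) uses a compiled core with the identical update
#' rule and noise draw order, so the two produce bit-identical trajectories
#' under the same seed.
#'
#' @param drift Function `(t, state) -> derivative vector`.
#' @param state0 Numeric initial state.
#' @param grid A [sim_grid()].
#' @param sigma Noise standard deviations in the velocity field
#'   (signal / sqrt(h)); scalar or one value per coordinate.
#' @param seed Optional integer; if supplied, `set.seed(seed)` is called so
#'   the noise stream is reproducible.
#'
#' @return Matrix with column `time_h` followed by one column per state
#'   coordinate, one row per recorded step.
#' @examples
#' g <- sim_grid(dt = 0.01, t_end = 10, transient = 0, record_stride = 10)
#' # damped harmonic oscillator, no noise
#' out <- integrate_sde(function(t, s) c(s[2], -s[1]), c(1, 0), g, sigma = 0)
#' @export
integrate_sde <- function(drift, state0, grid, sigma = 0, seed = NULL) {
  stopifnot(is.function(drift), is.numeric(state0), is_sim_grid(grid))
  d <- length(state0)
  sigma <- rep_len(as.numeric(sigma), d)
  if (any(!is.finite(sigma)) || any(sigma < 0))
    stop("`sigma` must be finite and >= 0")
  if (!is.null(seed)) set.seed(seed)

  dt <- grid$dt
  sdt <- sqrt(dt)
  noisy <- any(sigma > 0)
  stride <- grid$record_stride
  n_rec <- grid$n_steps %/% stride + 1L
  out <- matrix(NA_real_, n_rec, d)
  out[1L, ] <- state0
  s <- as.numeric(state0)
  rec <- 2L
  for (k in seq_len(grid$n_steps)) {
    t <- (k - 1L) * dt
    s <- s + drift(t, s) * dt
    if (noisy) s <- s + sigma * sdt * rnorm(d)
    if (k %% stride == 0L) {
      if (any(!is.finite(s)))
        stop(sprintf("non-finite state at integration step %d", k))
      out[rec, ] <- s
      rec <- rec + 1L
    }
  }
  times <- recorded_times(grid)
  res <- cbind(times, out)
  colnames(res) <- c("time_h", state_names(state0, d))
  res
}

#' Deterministic reference integration of an ODE system
#'
#' Adaptive-step solution (lsoda via \pkg{deSolve}) reported on the recorded
#' grid times. Serves as the deterministic oracle for [integrate_sde()] with
#' `sigma = 0` and as the solver for the Goodwin TTFL model.
#'
#' @param rhs Function `(t, state) -> derivative vector`.
#' @param state0 Numeric initial state.
#' @param grid A [sim_grid()].
#' @param rtol,atol Relative and absolute solver tolerances.
#'
#' @return Matrix with column `time_h` followed by one column per state
#'   coordinate.
#' @examples
#' g <- sim_grid(dt = 0.1, t_end = 10, transient = 0, record_stride = 1)
#' out <- integrate_ode(function(t, s) -0.3 * s, 1, g)
#' @export
integrate_ode <- function(rhs, state0, grid, rtol = 1e-8, atol = 1e-10) {
  stopifnot(is.function(rhs), is.numeric(state0), is_sim_grid(grid))
  times <- recorded_times(grid)
  sol <- deSolve::ode(
    y = as.numeric(state0), times = times,
    func = function(t, y, p) list(rhs(t, y)),
    parms = NULL, method = "lsoda", rtol = rtol, atol = atol
  )
  if (any(!is.finite(sol)))
    stop("non-finite state in ODE solution; check the right-hand side")
  res <- unclass(sol)
  attributes(res) <- attributes(res)["dim"]
  colnames(res) <- c("time_h", state_names(state0, length(state0)))
  res
}

state_names <- function(state0, d) {
  nm <- names(state0)
  if (is.null(nm) || anyNA(nm) || any(nm == "")) paste0("s", seq_len(d)) else nm
}
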