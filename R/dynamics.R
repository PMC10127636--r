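#' Integration settings
#'
#' Controls for the adaptive Runge-Kutta 5(4) integration. The defaults
#' integrate over a fixed horizon of 1000 time units -- long enough that
#' every surviving species' growth bracket has closed to numerical zero --
#' with tolerances far below any ecological signal in the downstream
#' metrics. `readout_floor` treats densities below it as extinct at readout
#' so that integration dust does not enter relative abundances.
#'
#' @param t_end positive integration horizon (time units of the model).
#' @param rel_tol,abs_tol positive local error tolerances.
#' @param max_steps positive integer cap on step attempts.
#' @param convergence_tol threshold on the infinity norm of the derivative
#'   at `t_end` below which the state is flagged converged.
#' @param readout_floor densities below this are zeroed at readout.
#' @param x0 initial density given to every species (the model does not
#'   prescribe initial conditions; all species start equal, strictly
#'   positive, below carrying capacity).
#' @return an object of class `integration_settings`.
#' @export
integration_settings <- function(t_end = 1000, rel_tol = 1e-8,
                                 abs_tol = 1e-8, max_steps = 500000L,
                                 convergence_tol = 1e-6,
                                 readout_floor = 1e-12, x0 = 0.1) {
  if (t_end <= 0 || rel_tol <= 0 || abs_tol <= 0 || convergence_tol <= 0)
    antago_error("tolerances and t_end must be > 0",
                 "invalid_parameter_error")
  if (max_steps < 1)
    antago_error("'max_steps' must be a positive integer",
                 "invalid_parameter_error")
  if (readout_floor < 0)
    antago_error("'readout_floor' must be >= 0", "invalid_parameter_error")
  if (x0 <= 0)
    antago_error("'x0' must be > 0", "invalid_parameter_error")
  structure(list(t_end = t_end, rel_tol = rel_tol, abs_tol = abs_tol,
                 max_steps = as.integer(max_steps),
                 convergence_tol = convergence_tol,
                 readout_floor = readout_floor, x0 = x0),
            class = "integration_settings")
}

#' Integrate a system to its long-run state
#'
#' Runs an adaptive explicit Runge-Kutta 5(4) scheme (Dormand-Prince pair,
#' FSAL, PI-free standard step controller) from a strictly positive initial
#' state to `t_end`. Any negative component produced by floating-point error
#' is clipped to 0 on step acceptance -- extinction is absorbing in the
#' model, so the clip is exact, not a fudge.
#'
#' @param system an `assembled_system`.
#' @param x0 strictly positive initial state; defaults to
#'   `settings$x0` for every species.
#' @param settings an [integration_settings()].
#' @return object of class `equilibrium_state`: `densities`, `converged`
#'   (derivative infinity-norm below `convergence_tol` at `t_end`),
#'   `t_end_used`, `steps`, `deriv_inf_norm`.
#' @examples
#' sys <- assemble_system(community_spec(2, 0, sigma = 0.3, A = 0.5, seed = 1))
#' integrate_system(sys)$densities
#' @export
integrate_system <- function(system, x0 = NULL,
                             settings = integration_settings()) {
  if (!inherits(system, "assembled_system"))
    antago_error("'system' must be an assembled_system", "invalid_input_error")
  N <- length(system$r)
  if (is.null(x0)) x0 <- rep(settings$x0, N)
  if (length(x0) != N)
    antago_error("'x0' length does not match system dimension",
                 "invalid_input_error")
  if (any(x0 <= 0))
    antago_error("'x0' must be strictly positive", "invalid_input_error")
  res <- cpp_integrate(system$alpha, system$r, x0, settings$t_end,
                       settings$rel_tol, settings$abs_tol,
                       settings$max_steps)
  if (!res$ok)
    stop(errorCondition(
      sprintf("integration failed after %d step attempts", res$steps),
      class = c("integration_failure_error", "antagosim_error"),
      steps = res$steps))
  structure(list(densities = res$densities,
                 converged = res$deriv_inf_norm < settings$convergence_tol,
                 t_end_used = settings$t_end, steps = res$steps,
                 deriv_inf_norm = res$deriv_inf_norm),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("equilibrium_state at t = %g (%s, %d step attempts)\n",
              x$t_end_used, if (x$converged) "converged" else "NOT converged",
              x$steps))
  print(x$densities)
  invisible(x)
}

#' Fixed-step forward-Euler integration (independent oracle)
#'
#' A deliberately naive integrator used to cross-check the adaptive scheme:
#' x <- x + dt * f(x), clipping negatives, for t_end/dt steps. Kept in plain
#' R, sharing no code with the production path.
#'
#' @param system an `assembled_system`.
#' @param x0 initial state vector.
#' @param dt fixed step size.
#' @param t_end horizon.
#' @return numeric vector of densities at `t_end`.
#' @export
integrate_euler <- function(system, x0, dt = 1e-3, t_end = 100) {
  alpha <- system$alpha
  r <- system$r
  x <- as.numeric(x0)
  nsteps <- round(t_end / dt)
  for (k in seq_len(nsteps)) {
    x <- x + dt * (r * x * (1 - drop(alpha %*% x)))
    x[x < 0] <- 0
  }
  x
}

#' Focal-species relative abundances
#'
#' Zeroes densities below `readout_floor`, then normalizes the first
#' `n_focal` densities to sum to 1. If every focal species is extinct the
#' replicate is degenerate and a classed error is raised so callers can
#' count (never silently drop) it.
#'
#' @param state an `equilibrium_state` (or plain density vector).
#' @param system the `assembled_system` the state came from.
#' @param settings an [integration_settings()] (supplies `readout_floor`).
#' @return numeric vector of length `n_focal` summing to 1.
#' @export
focal_relative_abundances <- function(state, system,
                                      settings = integration_settings()) {
  dens <- if (inherits(state, "equilibrium_state")) state$densities else
    as.numeric(state)
  if (length(dens) != length(system$r))
    antago_error("state dimension does not match system",
                 "invalid_input_error")
  n <- system$n_focal
  focal <- dens[seq_len(n)]
  focal[focal < settings$readout_floor] <- 0
  tot <- sum(focal)
  if (tot <= 0)
    stop(errorCondition(
      "all focal species extinct (degenerate community)",
      class = c("degenerate_community_error", "antagosim_error")))
  focal / tot
}
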