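#' Closed-form moments of the half-normal distribution
#'
#' For theta = |Z| sigma with Z standard normal: E(theta) = sigma
#' sqrt(2/pi), Var(theta) = sigma^2 (1 - 2/pi). The squared coefficient of
#' variation, Var/E^2 = pi/2 - 1, is scale-free.
#'
#' @param sigma positive scale parameter.
#' @return object of class `half_normal_moments` with `scale`, `mean`,
#'   `variance`.
#' @examples
#' half_normal_moments(0.3)
#' @export
half_normal_moments <- function(sigma) {
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    antago_error("'sigma' must be > 0", "invalid_parameter_error")
  structure(list(scale = sigma,
                 mean = sigma * sqrt(2 / pi),
                 variance = sigma^2 * (1 - 2 / pi)),
            class = "half_normal_moments")
}

#' @export
print.half_normal_moments <- function(x, ...) {
  cat(sprintf("half-normal(scale = %g): mean = %.6f, variance = %.6f\n",
              x$scale, x$mean, x$variance))
  invisible(x)
}

#' Coefficient of variation of the combined antagonist effect
#'
#' If each of m antagonist impacts on a focal species is an independent
#' draw theta from a positive finite-variance distribution, their sum beta
#' has E(beta) = E(theta) m and Var(beta) = Var(theta) m, hence
#' CV(beta) = sqrt(Var(theta) m) / (E(theta) m). For the half-normal this
#' collapses to sqrt(pi/2 - 1) / sqrt(m), independent of sigma: the relative
#' spread of the net antagonist burden shrinks as 1/sqrt(m), which is the
#' analytic heart of why many antagonists have convergent net effects.
#'
#' @param sigma positive half-normal scale (enters E and Var but cancels).
#' @param m integer >= 1, number of antagonists.
#' @return the coefficient of variation of beta.
#' @examples
#' cv_combined_effect(0.3, m = 1) # 0.7555
#' cv_combined_effect(0.3, m = 4) # half of m = 1
#' @export
cv_combined_effect <- function(sigma, m) {
  if (!is.numeric(m) || length(m) != 1 || m < 1 || m != floor(m))
    antago_error("'m' must be an integer >= 1", "invalid_parameter_error")
  mom <- half_normal_moments(sigma)
  sqrt(mom$variance * m) / (mom$mean * m)
}

#' Equilibrium of the symmetric competitive community
#'
#' For a community whose interaction matrix has diagonal 1 and all
#' off-diagonals equal to a (0 <= a < 1), the interior equilibrium solving
#' sum_j alpha_ij x_j = 1 is x_i = 1 / (1 + (n - 1) a) for every species.
#' Used as an oracle for the integrator.
#'
#' @param n integer >= 1, number of species.
#' @param a common off-diagonal interaction strength, in \[0, 1).
#' @return the per-species equilibrium density.
#' @export
symmetric_equilibrium <- function(n, a) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n))
    antago_error("'n' must be a positive integer", "invalid_parameter_error")
  if (a < 0)
    antago_error("'a' must be >= 0", "invalid_parameter_error")
  if (n >= 2 && a >= 1)
    stop(errorCondition(
      "no stable coexistence for a >= 1 with n >= 2",
      class = c("no_stable_coexistence_error", "antagosim_error")))
  1 / (1 + (n - 1) * a)
}
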