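#' Specify one random community draw
#'
#' A community spec bundles the four scalar parameters of the model with a
#' seed: `n` focal (bacterial) species, `m` antagonists (phages/plasmids/
#' MGEs), the half-normal scale `sigma` of antagonist impacts, and the focal
#' interspecific interaction modifier `A` (focal-focal off-diagonals are
#' Uniform(0, A/n)). The same spec and seed always yield the bit-identical
#' assembled system.
#'
#' @param n positive integer, number of focal species.
#' @param m nonnegative integer, number of antagonists.
#' @param sigma positive scale of the half-normal antagonist-impact
#'   distribution.
#' @param A positive interspecific interaction modifier.
#' @param seed nonnegative integer seed for the draw.
#' @return an object of class `community_spec`.
#' @examples
#' spec <- community_spec(n = 10, m = 3, sigma = 0.3, A = 0.5, seed = 1)
#' @export
community_spec <- function(n, m, sigma, A, seed = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n))
    antago_error("'n' must be a positive integer", "invalid_parameter_error")
  if (!is.numeric(m) || length(m) != 1 || m < 0 || m != floor(m))
    antago_error("'m' must be a nonnegative integer",
                 "invalid_parameter_error")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    antago_error("'sigma' must be > 0", "invalid_parameter_error")
  if (!is.numeric(A) || length(A) != 1 || A <= 0)
    antago_error("'A' must be > 0", "invalid_parameter_error")
  if (!is.numeric(seed) || length(seed) != 1 || seed < 0 ||
      seed != floor(seed))
    antago_error("'seed' must be a nonnegative integer",
                 "invalid_parameter_error")
  structure(
    list(n = as.integer(n), m = as.integer(m), sigma = as.numeric(sigma),
         A = as.numeric(A), seed = as.numeric(seed)),
    class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf("community_spec: n=%d focal, m=%d antagonists, sigma=%g, A=%g, seed=%.0f\n",
              x$n, x$m, x$sigma, x$A, x$seed))
  invisible(x)
}

#' Sample the focal-focal interaction block
#'
#' Diagonal entries are exactly 1 (intraspecific self-limitation); each
#' off-diagonal entry is an independent Uniform(0, A/n) draw, so larger
#' communities have individually weaker but more numerous competitive links.
#'
#' @inheritParams community_spec
#' @return an `n` x `n` matrix.
#' @export
sample_focal_block <- function(n, A, seed = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n))
    antago_error("'n' must be a positive integer", "invalid_parameter_error")
  if (!is.numeric(A) || length(A) != 1 || A <= 0)
    antago_error("'A' must be > 0", "invalid_parameter_error")
  cpp_sample_focal_block(as.integer(n), A, as.numeric(seed))
}

#' Sample the antagonist-impact block
#'
#' Each entry is the per-capita impact of one antagonist (column) on one
#' focal species (row), drawn half-normal: the absolute value of a
#' Normal(0, sigma^2) deviate, hence always a cost, never a benefit.
#'
#' @inheritParams community_spec
#' @return an `n` x `m` matrix (an `n` x 0 matrix when `m = 0`).
#' @export
sample_antagonist_impacts <- function(n, m, sigma, seed = 0) {
  if (!is.numeric(n) || length(n) != 1 || n < 1 || n != floor(n))
    antago_error("'n' must be a positive integer", "invalid_parameter_error")
  if (!is.numeric(m) || length(m) != 1 || m < 0 || m != floor(m))
    antago_error("'m' must be a nonnegative integer",
                 "invalid_parameter_error")
  if (!is.numeric(sigma) || length(sigma) != 1 || sigma <= 0)
    antago_error("'sigma' must be > 0", "invalid_parameter_error")
  if (m == 0) return(matrix(numeric(0), nrow = n, ncol = 0))
  cpp_sample_half_normal_matrix(as.integer(n), as.integer(m), sigma,
                                as.numeric(seed))
}

#' Sample intrinsic growth rates
#'
#' All species (focal and antagonist) receive strictly positive growth rates
#' drawn half-normal with scale 1; exact floating-point zeros are resampled.
#'
#' @param N positive integer, total number of species.
#' @param seed nonnegative integer seed.
#' @return a length-`N` positive numeric vector.
#' @export
sample_growth_rates <- function(N, seed = 0) {
  if (!is.numeric(N) || length(N) != 1 || N < 1 || N != floor(N))
    antago_error("'N' must be a positive integer", "invalid_parameter_error")
  drop(cpp_sample_half_normal_matrix(as.integer(N), 1L, 1.0,
                                     as.numeric(seed)))
}

#' Assemble the full interaction matrix and growth rates
#'
#' Builds the (n+m) x (n+m) system: indices 1..n are focal species, n+1..N
#' antagonists. The four blocks follow the model's construction rules:
#' focal-focal off-diagonals Uniform(0, A/n); antagonist impacts on focal
#' species half-normal N+(0, sigma); effects of focal species on antagonists
#' all 0 (antagonist densities are insensitive to which focal species are
#' present); all diagonal entries and all antagonist-antagonist interactions
#' exactly 1. Growth rates are half-normal N+(0, 1). The focal block and
#' focal growth rates depend only on (n, A, seed), so the matched m = 0
#' baseline of a paired run reuses them unchanged.
#'
#' @param spec a [community_spec()].
#' @return an object of class `assembled_system` with elements `alpha`
#'   (matrix, alpha\[i, j\] = effect of species j on species i), `r`,
#'   `n_focal`, `m_antagonist`.
#' @examples
#' sys <- assemble_system(community_spec(3, 2, sigma = 0.3, A = 0.5, seed = 7))
#' sys$alpha
#' @export
assemble_system <- function(spec) {
  if (!inherits(spec, "community_spec"))
    antago_error("'spec' must be a community_spec", "invalid_parameter_error")
  raw <- cpp_assemble(spec$n, spec$m, spec$sigma, spec$A, spec$seed)
  structure(
    list(alpha = raw$alpha, r = raw$r, n_focal = spec$n,
         m_antagonist = spec$m, spec = spec),
    class = "assembled_system")
}

#' @export
print.assembled_system <- function(x, ...) {
  cat(sprintf("assembled_system: %d focal + %d antagonist species (N = %d)\n",
              x$n_focal, x$m_antagonist, x$n_focal + x$m_antagonist))
  invisible(x)
}

# build an assembled_system directly from parts (fixtures, tests)
as_assembled_system <- function(alpha, r, n_focal, m_antagonist) {
  stopifnot(nrow(alpha) == ncol(alpha), length(r) == nrow(alpha),
            n_focal + m_antagonist == nrow(alpha))
  structure(list(alpha = alpha, r = r, n_focal = as.integer(n_focal),
                 m_antagonist = as.integer(m_antagonist), spec = NULL),
            class = "assembled_system")
}

#' Competitive Lotka-Volterra derivative
#'
#' Evaluates dx_i/dt = r_i x_i (1 - sum_j alpha_ij x_j) componentwise. At
#' x_i = 0 the derivative is exactly 0: extinction is absorbing.
#'
#' @param state nonnegative numeric vector of densities, length N.
#' @param system an `assembled_system`.
#' @return length-N numeric vector of time derivatives.
#' @export
lv_derivative <- function(state, system) {
  if (!inherits(system, "assembled_system"))
    antago_error("'system' must be an assembled_system", "invalid_input_error")
  if (length(state) != length(system$r))
    antago_error("'state' length does not match system dimension",
                 "invalid_input_error")
  if (any(state < 0))
    antago_error("'state' must be nonnegative", "invalid_input_error")
  system$r * state * (1 - drop(system$alpha %*% state))
}
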