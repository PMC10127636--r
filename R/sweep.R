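#' Define a parameter sweep grid
#'
#' A sweep evaluates every combination of (n, m, sigma, A) with m >= 1; the
#' m = 0 case is not a tile but the paired baseline inside every run. The
#' full published grid is n = 2, 4, ..., 20; m = 0, 1, ..., 10;
#' sigma = 0.1, 0.2, ..., 1; A = 0.1, 0.2, ..., 1 at 100,000 replicates per
#' tile -- far beyond a desktop budget, so `replicates` defaults to the
#' desk profile of 2,000 (same estimator, wider confidence bands).
#'
#' @param n_values,m_values,sigma_values,A_values nonempty numeric vectors
#'   of grid coordinates.
#' @param replicates paired runs per tile (>= 1).
#' @param root_seed nonnegative integer; every replicate stream is derived
#'   from it by a counter-based mixer, so results are independent of
#'   execution order.
#' @param settings an [integration_settings()].
#' @return an object of class `sweep_grid`.
#' @export
sweep_grid <- function(n_values, m_values, sigma_values, A_values,
                       replicates = 2000, root_seed = 0,
                       settings = integration_settings()) {
  if (length(n_values) == 0 || length(m_values) == 0 ||
      length(sigma_values) == 0 || length(A_values) == 0)
    antago_error("all grid value lists must be nonempty",
                 "invalid_parameter_error")
  if (any(n_values < 1) || any(n_values != floor(n_values)))
    antago_error("'n_values' must be positive integers",
                 "invalid_parameter_error")
  if (any(m_values < 0) || any(m_values != floor(m_values)))
    antago_error("'m_values' must be nonnegative integers",
                 "invalid_parameter_error")
  if (any(sigma_values <= 0))
    antago_error("'sigma_values' must be > 0", "invalid_parameter_error")
  if (any(A_values <= 0))
    antago_error("'A_values' must be > 0", "invalid_parameter_error")
  if (replicates < 1 || replicates != floor(replicates))
    antago_error("'replicates' must be a positive integer",
                 "invalid_parameter_error")
  structure(list(n_values = sort(unique(as.numeric(n_values))),
                 m_values = sort(unique(as.numeric(m_values))),
                 sigma_values = sort(unique(as.numeric(sigma_values))),
                 A_values = sort(unique(as.numeric(A_values))),
                 replicates = as.integer(replicates),
                 root_seed = as.numeric(root_seed),
                 settings = settings),
            class = "sweep_grid")
}

#' The published full grid
#' @param replicates,root_seed see [sweep_grid()].
#' @return a `sweep_grid` over n = 2..20 by 2, m = 0..10, sigma and A =
#'   0.1..1 by 0.1.
#' @export
full_grid <- function(replicates = 2000, root_seed = 0) {
  sweep_grid(seq(2, 20, by = 2), 0:10, seq(0.1, 1, by = 0.1),
             seq(0.1, 1, by = 0.1), replicates, root_seed)
}

#' The headline heat-map slice (n = 10, sigma = 0.3)
#' @param replicates,root_seed see [sweep_grid()].
#' @return a `sweep_grid` over m = 1..10 and A = 0.1..1 by 0.1.
#' @export
headline_grid <- function(replicates = 2000, root_seed = 0) {
  sweep_grid(10, 1:10, 0.3, seq(0.1, 1, by = 0.1), replicates, root_seed)
}

# canonical lexicographic tile table (m >= 1 only); row index feeds seeding
tile_table <- function(grid) {
  m_pos <- grid$m_values[grid$m_values >= 1]
  if (length(m_pos) == 0)
    antago_error("grid has no tiles with m >= 1", "invalid_parameter_error")
  tiles <- expand.grid(A = grid$A_values, sigma = grid$sigma_values,
                       m = m_pos, n = grid$n_values,
                       KEEP.OUT.ATTRS = FALSE)
  tiles[, c("n", "m", "sigma", "A")]
}

#' One paired with/without-antagonist run
#'
#' Draws a single focal community (focal interaction block and focal growth
#' rates) from `spec$seed`, simulates it twice -- once with the m antagonists
#' appended, once without -- from identical focal initial conditions, and
#' returns the Bray-Curtis dissimilarity and Kendall rank correlation
#' between the two focal compositions. With `pairing = "independent"` the
#' baseline is instead a fresh antagonist-free draw (sensitivity mode).
#'
#' @param spec a [community_spec()] with `m >= 1`.
#' @param settings an [integration_settings()].
#' @param pairing `"paired"` (matched baseline, default) or `"independent"`.
#' @return object of class `divergence_metrics`: `bray_curtis`,
#'   `kendall_standard`, `kendall_literal`, `converged_with`,
#'   `converged_without`. Raises a `degenerate_community_error` if all focal
#'   species go extinct in either arm.
#' @export
paired_run <- function(spec, settings = integration_settings(),
                       pairing = c("paired", "independent")) {
  pairing <- match.arg(pairing)
  if (!inherits(spec, "community_spec"))
    antago_error("'spec' must be a community_spec", "invalid_parameter_error")
  if (spec$m < 1)
    antago_error("paired_run requires m >= 1", "invalid_parameter_error")
  res <- cpp_paired_run(spec$n, spec$m, spec$sigma, spec$A, spec$seed,
                        settings$x0, settings$t_end, settings$rel_tol,
                        settings$abs_tol, settings$max_steps,
                        settings$convergence_tol, settings$readout_floor,
                        if (pairing == "paired") 0L else 1L)
  if (res[["degenerate"]] > 0.5)
    stop(errorCondition(
      sprintf("degenerate replicate (all focal extinct) for seed %.0f",
              spec$seed),
      class = c("degenerate_community_error", "antagosim_error")))
  structure(list(bray_curtis = res[["bray_curtis"]],
                 kendall_standard = res[["tau_std"]],
                 kendall_literal = res[["tau_lit"]],
                 converged_with = res[["converged_with"]] > 0.5,
                 converged_without = res[["converged_without"]] > 0.5),
            class = "divergence_metrics")
}

#' Divergence between the focal compositions of two assembled systems
#'
#' Integrates both systems from equal initial densities and scores the
#' focal compositions. Useful with hand-built systems (e.g. the zero-impact
#' fixture) where [paired_run()]'s random construction is bypassed.
#'
#' @param system,baseline `assembled_system` objects sharing `n_focal`.
#' @param settings an [integration_settings()].
#' @return a `divergence_metrics` object.
#' @export
paired_divergence <- function(system, baseline,
                              settings = integration_settings()) {
  if (system$n_focal != baseline$n_focal)
    antago_error("systems disagree on the number of focal species",
                 "invalid_input_error")
  sw <- integrate_system(system, settings = settings)
  sb <- integrate_system(baseline, settings = settings)
  p <- focal_relative_abundances(sw, system, settings)
  q <- focal_relative_abundances(sb, baseline, settings)
  structure(list(bray_curtis = bray_curtis(q, p),
                 kendall_standard = kendall_rank(q, p, "standard_tau_a"),
                 kendall_literal = kendall_rank(q, p, "paper_literal"),
                 converged_with = sw$converged,
                 converged_without = sb$converged),
            class = "divergence_metrics")
}

#' @export
print.divergence_metrics <- function(x, ...) {
  cat(sprintf("Bray-Curtis = %.4f, Kendall tau-a = %.4f (literal %.4f)\n",
              x$bray_curtis, x$kendall_standard, x$kendall_literal))
  invisible(x)
}

#' Seed stream for one replicate of one tile
#'
#' Exposes the counter-based derivation used inside [run_sweep()] so that a
#' single replicate can be reproduced in isolation: the community seed for
#' replicate `rep` of the tile at (1-based) row `tile_index` of the
#' canonical lexicographic tile table.
#'
#' @param root_seed the grid's root seed.
#' @param tile_index 1-based tile row in lexicographic (n, m, sigma, A)
#'   order.
#' @param rep 1-based replicate index.
#' @return a numeric seed (< 2^53).
#' @export
replicate_seed <- function(root_seed, tile_index, rep) {
  cpp_replicate_seed(as.numeric(root_seed), as.integer(tile_index),
                     as.integer(rep))
}

#' Run the paired with/without-antagonist sweep
#'
#' Executes `grid$replicates` paired runs for every tile (combination with
#' m >= 1), each from its own derived seed stream, and returns per-tile
#' means of both divergence metrics over the non-degenerate replicates,
#' with degenerate replicates counted, never silently dropped. Output rows
#' are in deterministic lexicographic (n, m, sigma, A) order.
#'
#' @param grid a [sweep_grid()].
#' @param kendall_variant which Kendall normalization enters
#'   `mean_kendall`.
#' @param pairing matched (`"paired"`) or independent baseline.
#' @return a `data.frame` (class `tile_summary`) with columns `n`, `m`,
#'   `sigma`, `A`, `mean_bray_curtis`, `mean_kendall`, `replicates_used`,
#'   `degenerate_count`.
#' @examples
#' \donttest{
#' g <- sweep_grid(4, 1:3, 0.3, 0.5, replicates = 50, root_seed = 1)
#' run_sweep(g)
#' }
#' @export
run_sweep <- function(grid,
                      kendall_variant = c("standard_tau_a", "paper_literal"),
                      pairing = c("paired", "independent")) {
  kendall_variant <- match.arg(kendall_variant)
  pairing <- match.arg(pairing)
  if (!inherits(grid, "sweep_grid"))
    antago_error("'grid' must be a sweep_grid", "invalid_parameter_error")
  tiles <- tile_table(grid)
  s <- grid$settings
  raw <- cpp_run_sweep(as.matrix(tiles), grid$replicates, grid$root_seed,
                       s$x0, s$t_end, s$rel_tol, s$abs_tol, s$max_steps,
                       s$convergence_tol, s$readout_floor,
                       if (pairing == "paired") 0L else 1L)
  out <- data.frame(
    n = as.integer(tiles$n), m = as.integer(tiles$m),
    sigma = tiles$sigma, A = tiles$A,
    mean_bray_curtis = raw[, 1],
    mean_kendall = if (kendall_variant == "standard_tau_a") raw[, 2]
                   else raw[, 3],
    replicates_used = as.integer(raw[, 4]),
    degenerate_count = as.integer(raw[, 5]))
  class(out) <- c("tile_summary", "data.frame")
  out
}

#' Monotone-trend check for a sequence of tile means
#'
#' A sequence "trends" in the given direction when (a) its last value lies
#' on the correct side of its first and (b) at least `min_pair_frac` of all
#' ordered pairs (i < j) move in that direction. Condition (b) is a
#' pairwise-concordance criterion (Kendall-style), which tolerates
#' Monte-Carlo noise between adjacent, nearly equal means without letting a
#' genuinely non-monotone sequence pass.
#'
#' @param values numeric sequence of means (ordered by the covariate).
#' @param direction `"decreasing"` or `"increasing"`.
#' @param min_pair_frac minimum fraction of ordered pairs that must move in
#'   `direction` (default 0.8).
#' @return logical.
#' @export
trend_holds <- function(values, direction = c("decreasing", "increasing"),
                        min_pair_frac = 0.8) {
  direction <- match.arg(direction)
  k <- length(values)
  if (k < 2) antago_error("need at least 2 values", "invalid_input_error")
  ij <- which(upper.tri(diag(k)), arr.ind = TRUE)
  d <- values[ij[, 2]] - values[ij[, 1]] # later minus earlier
  if (direction == "decreasing") {
    ends <- values[k] < values[1]
    frac <- mean(d < 0)
  } else {
    ends <- values[k] > values[1]
    frac <- mean(d > 0)
  }
  ends && frac >= min_pair_frac
}
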