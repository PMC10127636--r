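#' Bray-Curtis dissimilarity between two relative-abundance vectors
#'
#' For normalized compositions this is 1 - sum_i min(p_i, q_i): 0 for
#' identical communities, 1 for disjoint support. Equivalent to half the L1
#' distance on normalized vectors.
#'
#' @param p,q numeric vectors of equal length, each summing to 1 (within
#'   1e-9) with nonnegative entries.
#' @return a number in \[0, 1\].
#' @examples
#' bray_curtis(c(0.7, 0.3), c(0.5, 0.5)) # 0.2
#' @export
bray_curtis <- function(p, q) {
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    antago_error("'p' and 'q' must have equal length", "invalid_input_error")
  if (any(p < 0) || any(q < 0))
    antago_error("compositions must be nonnegative", "invalid_input_error")
  if (abs(sum(p) - 1) > 1e-9 || abs(sum(q) - 1) > 1e-9)
    antago_error("compositions must each sum to 1 (within 1e-9)",
                 "invalid_input_error")
  1 - sum(pmin(p, q))
}

#' Kendall rank correlation between two compositions
#'
#' Counts concordant (nc) and discordant (nd) species pairs over all
#' n(n-1)/2 unordered pairs; pairs tied in either vector count toward
#' neither. The default `standard_tau_a` variant normalizes by the pair
#' count, giving the usual tau-a in \[-1, 1\]. The `paper_literal` variant
#' divides by n, the species count, as sometimes printed; it is not bounded
#' by 1 for n >= 4 and is provided only for replication attempts.
#'
#' @param p,q numeric vectors of equal length >= 2.
#' @param variant `"standard_tau_a"` (default) or `"paper_literal"`.
#' @return a number; in \[-1, 1\] for `standard_tau_a`.
#' @examples
#' kendall_rank(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2)) # 1/3
#' @export
kendall_rank <- function(p, q,
                         variant = c("standard_tau_a", "paper_literal")) {
  variant <- match.arg(variant)
  p <- as.numeric(p); q <- as.numeric(q)
  if (length(p) != length(q))
    antago_error("'p' and 'q' must have equal length", "invalid_input_error")
  n <- length(p)
  if (n < 2)
    antago_error("need at least 2 species", "invalid_input_error")
  ij <- which(upper.tri(diag(n)), arr.ind = TRUE)
  dp <- p[ij[, 1]] - p[ij[, 2]]
  dq <- q[ij[, 1]] - q[ij[, 2]]
  s <- sign(dp) * sign(dq) # 0 when tied in either vector
  nc <- sum(s > 0)
  nd <- sum(s < 0)
  switch(variant,
         standard_tau_a = (nc - nd) / (n * (n - 1) / 2),
         paper_literal = (nc - nd) / n)
}

#' Shannon diversity of a composition
#'
#' H = -sum over species with p_i > 0 of p_i log(p_i), natural log.
#' Zero-abundance species contribute nothing.
#'
#' @param p numeric vector of relative abundances summing to 1.
#' @return nonnegative number, at most log(length(p)).
#' @examples
#' shannon_diversity(c(0.5, 0.25, 0.25)) # 1.0397
#' @export
shannon_diversity <- function(p) {
  p <- as.numeric(p)
  if (any(p < 0))
    antago_error("abundances must be nonnegative", "invalid_input_error")
  if (abs(sum(p) - 1) > 1e-9)
    antago_error("composition must sum to 1 (within 1e-9)",
                 "invalid_input_error")
  pos <- p[p > 0]
  -sum(pos * log(pos))
}

#' Pielou evenness of a composition
#'
#' J = H / log(S) with S the number of species (vector length); 1 when all
#' species are equally abundant, approaching 0 under single-species
#' dominance. Base-invariant. Undefined for S < 2.
#'
#' @param p numeric vector of relative abundances, length >= 2, summing to 1.
#' @return a number in \[0, 1\].
#' @export
evenness <- function(p) {
  p <- as.numeric(p)
  if (length(p) < 2)
    antago_error("evenness needs at least 2 species (log S = 0 otherwise)",
                 "invalid_input_error")
  # J <= 1 mathematically; rounding in H/log(S) can overshoot by ~1e-16,
  # so clamp at the bound (uniform compositions then give exactly 1)
  min(shannon_diversity(p) / log(length(p)), 1)
}
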