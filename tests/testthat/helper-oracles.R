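# Independent oracles shared across test files. These deliberately share no
# code with the package internals they check.

# brute-force Kendall: enumerate every unordered pair
brute_kendall <- function(p, q, variant = "standard_tau_a") {
  n <- length(p)
  nc <- 0L
  nd <- 0L
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      dp <- p[i] - p[j]
      dq <- q[i] - q[j]
      if (dp == 0 || dq == 0) next
      if ((dp > 0) == (dq > 0)) nc <- nc + 1L else nd <- nd + 1L
    }
  }
  if (variant == "standard_tau_a") (nc - nd) / (n * (n - 1) / 2)
  else (nc - nd) / n
}

# random composition on the simplex
random_composition <- function(k) {
  v <- runif(k)
  v / sum(v)
}

# logistic closed form for a single species with r and carrying capacity 1
logistic_closed_form <- function(x0, r, t) {
  1 / (1 + ((1 - x0) / x0) * exp(-r * t))
}
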