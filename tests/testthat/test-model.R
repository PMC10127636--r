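test_that("parameter validation rejects bad specs", {
  expect_error(community_spec(0, 1, 0.3, 0.5), class = "invalid_parameter_error")
  expect_error(community_spec(3, -1, 0.3, 0.5), class = "invalid_parameter_error")
  expect_error(community_spec(3, 1, 0, 0.5), class = "invalid_parameter_error")
  expect_error(community_spec(3, 1, 0.3, -2), class = "invalid_parameter_error")
  expect_error(sample_focal_block(-1, 0.5), class = "invalid_parameter_error")
  expect_error(sample_antagonist_impacts(3, -1, 0.3), class = "invalid_parameter_error")
  expect_error(sample_growth_rates(0), class = "invalid_parameter_error")
})

test_that("assembled systems satisfy every block invariant", {
  cases <- list(c(2, 0), c(1, 1), c(3, 2), c(10, 10), c(20, 5))
  for (cs in cases) {
    n <- cs[1]; m <- cs[2]; N <- n + m
    spec <- community_spec(n, m, sigma = 0.3, A = 0.5, seed = 100 + n + m)
    sys <- assemble_system(spec)
    expect_equal(dim(sys$alpha), c(N, N))
    expect_identical(unname(diag(sys$alpha)), rep(1, N))
    focal <- sys$alpha[seq_len(n), seq_len(n), drop = FALSE]
    off <- focal[row(focal) != col(focal)]
    expect_true(all(off >= 0 & off <= 0.5 / n))
    if (m > 0) {
      ant <- seq(n + 1, N)
      expect_true(all(sys$alpha[ant, seq_len(n)] == 0))
      expect_true(all(sys$alpha[ant, ant] == 1))
      expect_true(all(sys$alpha[seq_len(n), ant] >= 0))
    }
    expect_true(all(sys$r > 0))
  }
})

test_that("assembly is deterministic in the seed and varies across seeds", {
  spec <- community_spec(5, 3, 0.3, 0.5, seed = 9)
  s1 <- assemble_system(spec)
  s2 <- assemble_system(spec)
  expect_identical(s1$alpha, s2$alpha)
  expect_identical(s1$r, s2$r)
  s3 <- assemble_system(community_spec(5, 3, 0.3, 0.5, seed = 10))
  expect_false(identical(s1$alpha, s3$alpha))
  expect_identical(sample_focal_block(4, 0.5, seed = 3),
                   sample_focal_block(4, 0.5, seed = 3))
  expect_identical(sample_growth_rates(6, seed = 3),
                   sample_growth_rates(6, seed = 3))
})

test_that("the m = 0 reduction shares the focal block and focal growth rates", {
  spec <- community_spec(3, 2, sigma = 0.3, A = 0.5, seed = 77)
  full <- assemble_system(spec)
  base <- assemble_system(community_spec(3, 0, sigma = 0.3, A = 0.5, seed = 77))
  expect_identical(full$alpha[1:3, 1:3], base$alpha)
  expect_identical(full$r[1:3], base$r)
  # focal block is the stream prefix, so it matches the standalone sampler
  expect_identical(full$alpha[1:3, 1:3], sample_focal_block(3, 0.5, seed = 77))
})

test_that("edge cases: n = 1 focal block and m = 0 impacts", {
  expect_identical(sample_focal_block(1, 0.7, seed = 1), matrix(1, 1, 1))
  blk <- sample_antagonist_impacts(4, 0, 0.3, seed = 1)
  expect_equal(dim(blk), c(4, 0))
})

test_that("empirical moments match the closed forms at 1e6 draws", {
  # focal off-diagonals ~ Uniform(0, A/n): mean b/2, sd b/sqrt(12)
  n <- 1000; A <- 0.5; b <- A / n
  blk <- sample_focal_block(n, A, seed = 5)
  off <- blk[row(blk) != col(blk)]
  se <- (b / sqrt(12)) / sqrt(length(off))
  expect_lt(abs(mean(off) - b / 2), 5 * se)
  expect_true(all(off >= 0 & off <= b))

  # antagonist impacts ~ half-normal(sigma): mean sigma*sqrt(2/pi),
  # variance sigma^2*(1 - 2/pi)
  sigma <- 0.3
  imp <- sample_antagonist_impacts(1000, 1000, sigma, seed = 6)
  hn_sd <- sigma * sqrt(1 - 2 / pi)
  se_mean <- hn_sd / sqrt(length(imp))
  expect_lt(abs(mean(imp) - sigma * sqrt(2 / pi)), 5 * se_mean)
  expect_lt(abs(var(as.numeric(imp)) - sigma^2 * (1 - 2 / pi)), 5e-4)

  # growth rates ~ half-normal(1), strictly positive
  r <- sample_growth_rates(1e6, seed = 7)
  expect_true(all(r > 0))
  expect_lt(abs(mean(r) - sqrt(2 / pi)), 5 * sqrt(1 - 2 / pi) / sqrt(1e6))
})

test_that("lv_derivative matches hand evaluations and boundary behaviour", {
  one <- as_sys <- generate_fixture("single-logistic")$system
  expect_equal(lv_derivative(0.5, one), 0.25)
  sys <- assemble_system(community_spec(4, 2, 0.3, 0.5, seed = 3))
  expect_identical(lv_derivative(rep(0, 6), sys), rep(0, 6))
  # any state solving alpha x = 1 rowwise has zero derivative
  pair <- generate_fixture("symmetric-pair")$system
  expect_equal(lv_derivative(rep(2 / 3, 2), pair), rep(0, 2),
               tolerance = 1e-12)
  # extinction is absorbing: zero components keep zero derivative
  x <- c(0, 0.4, 0.2, 0, 0.1, 0.3)
  expect_identical(lv_derivative(x, sys)[c(1, 4)], c(0, 0))
  expect_error(lv_derivative(c(0.1, 0.2), sys), class = "invalid_input_error")
})
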