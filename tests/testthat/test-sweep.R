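test_that("antagonists with zero impact leave the focal community unchanged", {
  fx <- generate_fixture("zero-impact-antagonists", seed = 5)
  dv <- paired_divergence(fx$system, fx$baseline)
  # the two arms differ in dimension, so step sequences differ; agreement is
  # bounded by the integration tolerance, far below any ecological signal
  expect_lt(dv$bray_curtis, 1e-6)
  expect_identical(dv$kendall_standard, 1)
})

test_that("an arm compared against itself gives (0, 1)", {
  sys <- assemble_system(community_spec(4, 1, 0.3, 0.5, seed = 2))
  dv <- paired_divergence(sys, sys)
  expect_identical(dv$bray_curtis, 0)
  expect_identical(dv$kendall_standard, 1)
})

test_that("a targeted antagonist suppresses its host (Euler cross-check)", {
  # two focal competitors; the antagonist hits only species 1
  a <- 0.2
  alpha_with <- rbind(c(1, a, 0.5),
                      c(a, 1, 0),
                      c(0, 0, 1))
  alpha_base <- alpha_with[1:2, 1:2]
  sys_with <- antagosim:::as_assembled_system(alpha_with, rep(1, 3), 2L, 1L)
  sys_base <- antagosim:::as_assembled_system(alpha_base, rep(1, 2), 2L, 0L)
  dv <- paired_divergence(sys_with, sys_base)
  expect_gt(dv$bray_curtis, 0)
  # independent route: brute-force Euler on both arms
  xw <- integrate_euler(sys_with, rep(0.1, 3), dt = 1e-3, t_end = 200)
  xb <- integrate_euler(sys_base, rep(0.1, 2), dt = 1e-3, t_end = 200)
  p <- xw[1:2] / sum(xw[1:2])
  q <- xb / sum(xb)
  expect_lt(p[1], q[1]) # species 1's share drops under its antagonist
  expect_equal(dv$bray_curtis, bray_curtis(q, p), tolerance = 1e-3)
})

test_that("paired_run equals the hand-paired construction bit for bit", {
  spec <- community_spec(6, 3, sigma = 0.3, A = 0.5, seed = 321)
  pr <- paired_run(spec)
  sys_with <- assemble_system(spec)
  sys_base <- assemble_system(community_spec(6, 0, 0.3, 0.5, seed = 321))
  dv <- paired_divergence(sys_with, sys_base)
  expect_identical(pr$bray_curtis, dv$bray_curtis)
  expect_identical(pr$kendall_standard, dv$kendall_standard)
  expect_identical(pr$kendall_literal, dv$kendall_literal)
})

test_that("independent pairing uses a different baseline draw", {
  spec <- community_spec(6, 3, sigma = 0.3, A = 0.5, seed = 321)
  pr_paired <- paired_run(spec)
  pr_indep <- paired_run(spec, pairing = "independent")
  expect_false(identical(pr_paired$bray_curtis, pr_indep$bray_curtis))
})

test_that("overwhelming antagonist load raises a degenerate-community error", {
  # under a crushing antagonist load both focal species decay to the
  # absolute-tolerance scale; a readout floor above it declares them extinct
  spec <- community_spec(2, 10, sigma = 50, A = 0.5, seed = 8)
  s <- integration_settings(readout_floor = 1e-6)
  expect_error(paired_run(spec, settings = s),
               class = "degenerate_community_error")
})

test_that("run_sweep counts degenerate replicates instead of aborting", {
  g <- sweep_grid(2, 10, 50, 0.5, replicates = 20, root_seed = 8,
                  settings = integration_settings(readout_floor = 1e-6))
  res <- run_sweep(g)
  expect_equal(res$replicates_used + res$degenerate_count, 20L)
  expect_gt(res$degenerate_count, 0L)
})

test_that("run_sweep is reproducible and lexicographically ordered", {
  g <- sweep_grid(c(4, 2), c(2, 1), 0.3, c(0.5, 0.2), replicates = 25,
                  root_seed = 3)
  r1 <- run_sweep(g)
  r2 <- run_sweep(g)
  expect_identical(r1, r2)
  ord <- order(r1$n, r1$m, r1$sigma, r1$A)
  expect_identical(ord, seq_len(nrow(r1)))
  expect_equal(nrow(r1), 8)
})

test_that("tile means reproduce from replicate_seed + paired_run", {
  g <- sweep_grid(5, c(1, 2), 0.3, 0.5, replicates = 15, root_seed = 12)
  res <- run_sweep(g)
  for (k in seq_len(nrow(res))) {
    bc <- vapply(seq_len(15), function(rep) {
      seed <- replicate_seed(12, k, rep)
      paired_run(community_spec(res$n[k], res$m[k], res$sigma[k], res$A[k],
                                seed = seed))$bray_curtis
    }, numeric(1))
    expect_equal(res$mean_bray_curtis[k], mean(bc), tolerance = 1e-12)
  }
})

test_that("kendall variant selection propagates to tile means", {
  # n = 4: the pair count (6) differs from n, unlike n = 3 where they tie
  g <- sweep_grid(4, 2, 0.3, 0.5, replicates = 10, root_seed = 4)
  std <- run_sweep(g, kendall_variant = "standard_tau_a")
  lit <- run_sweep(g, kendall_variant = "paper_literal")
  expect_identical(std$mean_bray_curtis, lit$mean_bray_curtis)
  expect_false(identical(std$mean_kendall, lit$mean_kendall))
})

test_that("trend_holds detects direction and tolerates adjacent noise", {
  expect_true(trend_holds(c(5, 4, 3, 2, 1), "decreasing"))
  expect_true(trend_holds(c(5, 4, 4.05, 2, 1), "decreasing"))
  expect_false(trend_holds(c(1, 2, 3, 4, 5), "decreasing"))
  expect_true(trend_holds(c(1, 2, 3, 4, 5), "increasing"))
  expect_false(trend_holds(c(1, 3, 2, 2.5, 1.2), "increasing"))
  expect_error(trend_holds(1), class = "invalid_input_error")
})
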