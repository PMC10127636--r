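test_that("bray_curtis matches hand values and validates input", {
  expect_identical(bray_curtis(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_identical(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_equal(bray_curtis(c(0.7, 0.3), c(0.5, 0.5)), 0.2)
  expect_error(bray_curtis(c(0.5, 0.5), c(1, 0, 0)),
               class = "invalid_input_error")
  expect_error(bray_curtis(c(0.7, 0.7), c(0.5, 0.5)),
               class = "invalid_input_error")
})

test_that("bray_curtis is symmetric and equals half the L1 distance", {
  set.seed(11)
  for (k in c(2, 3, 5, 8, 12)) {
    p <- random_composition(k)
    q <- random_composition(k)
    expect_identical(bray_curtis(p, q), bray_curtis(q, p))
    expect_equal(bray_curtis(p, q), sum(abs(p - q)) / 2, tolerance = 1e-12)
    expect_true(bray_curtis(p, q) >= 0 && bray_curtis(p, q) <= 1)
  }
})

test_that("bray_curtis agrees with vegan's implementation", {
  skip_if_not_installed("vegan")
  set.seed(12)
  for (k in c(3, 6, 10)) {
    p <- random_composition(k)
    q <- random_composition(k)
    ref <- as.numeric(vegan::vegdist(rbind(p, q), method = "bray"))
    expect_equal(bray_curtis(p, q), ref, tolerance = 1e-12)
  }
})

test_that("kendall_rank matches hand-enumerated examples", {
  expect_identical(kendall_rank(c(0.5, 0.3, 0.2), c(0.4, 0.35, 0.25)), 1)
  expect_identical(kendall_rank(c(0.5, 0.3, 0.2), c(0.2, 0.3, 0.5)), -1)
  # one swapped pair among three species: nc = 2, nd = 1
  expect_equal(kendall_rank(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2)), 1 / 3)
  expect_equal(kendall_rank(c(0.5, 0.3, 0.2), c(0.3, 0.5, 0.2),
                            variant = "paper_literal"), 1 / 3)
  expect_error(kendall_rank(1, 1), class = "invalid_input_error")
})

test_that("kendall_rank agrees with brute-force enumeration and stats::cor", {
  set.seed(13)
  for (rep in 1:50) {
    k <- sample(2:8, 1)
    p <- random_composition(k)
    q <- random_composition(k)
    expect_identical(kendall_rank(p, q), brute_kendall(p, q))
    expect_identical(kendall_rank(p, q, "paper_literal"),
                     brute_kendall(p, q, "paper_literal"))
    # continuous draws are tie-free, so tau-a coincides with stats::cor's tau
    expect_equal(kendall_rank(p, q), cor(p, q, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("ties count toward neither concordant nor discordant", {
  # pair (1,2) tied in p; pairs (1,3) and (2,3) concordant
  expect_equal(kendall_rank(c(0.4, 0.4, 0.2), c(0.5, 0.3, 0.2)), 2 / 3)
  # everything tied in q: zero pairs counted
  expect_identical(kendall_rank(c(0.5, 0.3, 0.2), c(1, 1, 1) / 3), 0)
})

test_that("paper-literal normalization exceeds 1 for larger concordant sets", {
  p <- sort(random_composition(6), decreasing = TRUE)
  expect_identical(kendall_rank(p, p, "paper_literal"), 15 / 6)
  expect_identical(kendall_rank(p, p), 1)
})

test_that("shannon_diversity matches closed forms", {
  expect_equal(shannon_diversity(rep(1 / 3, 3)), log(3))
  expect_identical(shannon_diversity(c(1, 0, 0)), 0)
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.5 * log(2))
  expect_equal(shannon_diversity(c(0.5, 0.25, 0.25)), 1.0397, tolerance = 1e-4)
  expect_error(shannon_diversity(c(-0.1, 1.1)), class = "invalid_input_error")
})

test_that("evenness is normalized, permutation-invariant and bounded", {
  expect_identical(evenness(rep(0.25, 4)), 1)
  expect_equal(evenness(c(0.5, 0.25, 0.25)), 1.5 * log(2) / log(3))
  expect_equal(evenness(c(0.5, 0.25, 0.25)), 0.9464, tolerance = 1e-4)
  set.seed(14)
  for (k in c(3, 5, 9)) {
    p <- random_composition(k)
    expect_equal(evenness(p), evenness(sample(p)), tolerance = 1e-12)
    expect_true(evenness(p) >= 0 && evenness(p) <= 1)
  }
  # dominance drives J towards 0
  expect_lt(evenness(c(1 - 1e-9, 1e-9)), 1e-7)
  expect_error(evenness(1), class = "invalid_input_error")
})
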