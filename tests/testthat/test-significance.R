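test_that("sampled permutation p agrees with the exhaustive ordering oracle", {
  set.seed(11)
  for (k in 1:3) {
    a <- rnorm(3); b <- rnorm(3)
    frac <- exact_null_fraction(a, b)       # over all 6 x 6 joint orderings
    B <- 10000L
    p <- permutation_pvalue(a, b, n_perm = B, seed = 100 + k)$p_value
    # the add-one estimator centres on (1 + B * frac) / (B + 1)
    mc_se <- sqrt(frac * (1 - frac) / B)
    expect_lt(abs(p - (1 + B * frac) / (B + 1)), 3 * mc_se + 1e-4)
  }
})

test_that("identical series give the minimal attainable p, never zero", {
  a <- scale_series(time_series(c(0, 2, 1, 4, 3)))
  pn <- permutation_pvalue(a, a, n_perm = 199, seed = 1)
  expect_equal(pn$observed_distance, 0)
  expect_gt(pn$p_value, 0)
  expect_lte(pn$p_value, 1)
  expect_equal(pn$p_value,
               (1 + sum(pn$null_distances <= 0)) / 200)
})

test_that("permutation p-values are reproducible and seed-driven", {
  set.seed(3)
  a <- rnorm(7); b <- rnorm(7)
  p1 <- permutation_pvalue(a, b, 99, seed = 42)
  p2 <- permutation_pvalue(a, b, 99, seed = 42)
  p3 <- permutation_pvalue(a, b, 99, seed = 43)
  expect_identical(p1$null_distances, p2$null_distances)
  expect_false(identical(p1$null_distances, p3$null_distances))
})

test_that("permutation p-values are calibrated under an exchangeable null", {
  set.seed(2024)
  n_pairs <- 400L
  p <- vapply(seq_len(n_pairs), function(k) {
    a <- scale_series(time_series(rnorm(9)))
    b <- scale_series(time_series(rnorm(9)))
    permutation_pvalue(a, b, n_perm = 199, seed = k)$p_value
  }, numeric(1))
  frac <- mean(p <= 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("BH adjustment matches its worked examples", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.5)), c(0.04, 0.04, 0.04, 0.5))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.05, 7)), rep(0.05, 7))
  expect_error(bh_adjust(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_adjust(c(0.1, 1.2)), "\\(0, 1\\]")
  expect_identical(bh_adjust(numeric(0)), numeric(0))
})

test_that("BH adjustment matches an independent step-up oracle", {
  set.seed(5)
  for (k in 1:200) {
    m <- sample(1:500, 1)
    p <- runif(m)
    q <- bh_adjust(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q <= 1))
    # order equivariance: permuting inputs permutes outputs identically
    ord <- sample.int(m)
    expect_equal(bh_adjust(p[ord]), q[ord], tolerance = 1e-12)
  }
})

test_that("seed mixing is deterministic and stays below 2^31", {
  h1 <- warpscreen:::mix_seed(1L, "gene_A")
  expect_identical(h1, warpscreen:::mix_seed(1L, "gene_A"))
  expect_false(h1 == warpscreen:::mix_seed(1L, "gene_B"))
  expect_false(h1 == warpscreen:::mix_seed(2L, "gene_A"))
  seeds <- vapply(1:500, function(i)
    warpscreen:::mix_seed(i, paste0("e", i)), integer(1))
  expect_true(all(seeds >= 0 & seeds < 2^31))
})
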