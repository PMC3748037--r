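test_that("smooth series are deterministic, finite, and hit their knots", {
  s1 <- smooth_series(20, seed = 1)
  expect_identical(s1, smooth_series(20, seed = 1))
  expect_length(s1, 20)
  expect_true(all(is.finite(s1)))
  expect_error(smooth_series(3), ">= 4")
  # spline interpolation reproduces the knot draws exactly
  set.seed(9); yk <- rnorm(4)
  xk <- seq(1, 20, length.out = 4)
  s2 <- smooth_series(20, seed = 9)
  expect_equal(s2[round(xk)[c(1, 4)]], yk[c(1, 4)])  # integer knots
})

test_that("smooth series are smoother than white noise", {
  set.seed(17)
  ac1 <- function(x) cor(x[-length(x)], x[-1])
  smooth_ac <- mean(vapply(1:300, function(k)
    ac1(smooth_series(20)), numeric(1)))
  iid_ac <- mean(vapply(1:300, function(k) ac1(rnorm(20)), numeric(1)))
  expect_gt(smooth_ac, 0.5)
  expect_gt(smooth_ac, iid_ac + 0.3)
})

test_that("benchmark layout matches the stated configuration", {
  bm <- make_benchmark(n_matched = 400, n_decoys = 40, seed = 2)
  expect_equal(dim(bm$setA), c(440, 20))
  expect_equal(dim(bm$setB), c(440, 20))
  expect_equal(sum(bm$truth$matched), 400)
  cells <- table(bm$truth$shift, bm$truth$noise_level)
  expect_true(all(cells == 4))             # balanced 10 x 10 grid
  expect_equal(bm$mother_length, 29)
  expect_identical(bm$setA, make_benchmark(400, 40, seed = 2)$setA)
  expect_true(all(is.na(bm$truth$shift[!bm$truth$matched])))
  expect_warning(make_benchmark(n_matched = 401, n_decoys = 0, seed = 1),
                 "truncated")
})

test_that("zero corruption reproduces set A exactly", {
  bm <- make_benchmark(n_matched = 10, n_decoys = 0, max_shift = 0,
                       noise_multipliers = 0, seed = 3)
  expect_equal(bm$setB, bm$setA)
})

test_that("intended paths match their construction and the aligner", {
  expect_equal(unname(intended_path(5, 0)), cbind(1:5, 1:5))
  expect_equal(unname(intended_path(5, 2)),
               rbind(c(1, 1), c(2, 1), c(3, 1), c(4, 2), c(5, 3),
                     c(5, 4), c(5, 5)))
  expect_error(intended_path(5, 5), "\\[0, length\\)")
  for (shift in 0:9) expect_valid_path(intended_path(20, shift), 20L, 20L)

  # on noiseless shifted windows of a smooth mother series the aligner
  # recovers the intended path nearly always at small shifts; at large
  # shifts an equally long path that delays mid-course (where the series is
  # flat) is often genuinely cheaper, so recovery is only required to stay
  # well above chance there
  set.seed(23)
  small <- c(0L, 0L); large <- c(0L, 0L)  # hits, trials
  for (k in 1:400) {
    shift <- sample(0:9, 1)
    mother <- smooth_series(29)
    a <- mother[1:20]; b <- mother[(1 + shift):(20 + shift)]
    al <- dtw_align(a, b)
    hit <- identical(unname(al$path), unname(intended_path(20, shift)))
    if (shift <= 2) small <- small + c(hit, 1L) else large <- large + c(hit, 1L)
  }
  expect_gte(small[1] / small[2], 0.95)
  expect_gte(large[1] / large[2], 0.5)
})

test_that("evaluation grids score detection and exact-path recovery", {
  bm <- make_benchmark(n_matched = 60, n_decoys = 10, max_shift = 2,
                       noise_multipliers = c(0, 0.5), seed = 4)
  sc <- screen_matched(bm$setA, bm$setB, n_perm = 199, seed = 5)
  ev <- evaluate_benchmark(bm, sc)
  expect_equal(dim(ev$detection_pct), c(2, 3))
  expect_true(all(ev$detection_pct >= 0 & ev$detection_pct <= 100))
  # zero-corruption cell: identical pairs, always found, always exact
  expect_equal(ev$detection_pct["1", "0"], 100)
  expect_equal(ev$exact_path_pct["1", "0"], 100)
  # an impossible threshold empties the detection grid
  ev0 <- evaluate_benchmark(bm, sc, fdr = 0)
  expect_true(all(ev0$detection_pct == 0))
  expect_equal(ev0$decoy_detection_pct, 0)
  # label coverage is enforced
  sc_sub <- sc; sc_sub$records <- sc$records[-1, ]
  expect_error(evaluate_benchmark(bm, sc_sub), "cover")
})

test_that("smooth decoys inflate detection; white-noise decoys do not", {
  set.seed(29)
  n <- 150L
  p_smooth <- vapply(seq_len(n), function(k)
    permutation_pvalue(scale_series(time_series(smooth_series(20))),
                       scale_series(time_series(smooth_series(20))),
                       n_perm = 99, seed = k)$p_value, numeric(1))
  p_iid <- vapply(seq_len(n), function(k)
    permutation_pvalue(scale_series(time_series(rnorm(20))),
                       scale_series(time_series(rnorm(20))),
                       n_perm = 99, seed = k)$p_value, numeric(1))
  se <- sqrt(0.05 * 0.95 / n)
  expect_gt(mean(p_smooth <= 0.05), 0.05 + 3 * se)
  expect_lte(mean(p_iid <= 0.05), 0.05 + 3 * se)
})
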