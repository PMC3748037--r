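test_that("scaling modes behave as documented", {
  expect_equal(scale_series(time_series(c(1, 2, 3)))$values, c(-1, 0, 1))
  expect_equal(scale_series(time_series(c(5, 5, 5)), "none")$values,
               c(5, 5, 5))
  expect_equal(scale_series(time_series(c(2, 4, 9)), "mean_center")$values,
               c(2, 4, 9) - 5)
  expect_error(scale_series(time_series(c(5, 5, 5), label = "flatgene")),
               "flatgene")
  s <- scale_series(time_series(c(1, 5, 2), timepoints = c(0, 2, 24),
                                label = "g"))
  expect_equal(s$timepoints, c(0, 2, 24))
  expect_equal(s$label, "g")
})

test_that("time_series enforces its invariants", {
  expect_error(time_series(1), "at least 2")
  expect_error(time_series(c(1, 2), timepoints = c(2, 1)),
               "strictly increasing")
  expect_error(time_series(c(1, NA)), "non-finite")
  expect_error(time_series(1:3, timepoints = 1:2), "length")
})

test_that("identical series align along the diagonal with zero distance", {
  al <- dtw_align(c(1, 2, 3), c(1, 2, 3))
  expect_equal(al$distance, 0)
  expect_equal(unname(al$path), cbind(1:3, 1:3))
})

test_that("a delayed step series aligns at zero cost via the known path", {
  al <- dtw_align(c(0, 0, 1), c(0, 1, 1))
  expect_equal(al$distance, 0)
  expect_equal(unname(al$path), rbind(c(1, 1), c(2, 1), c(3, 2), c(3, 3)))
  # the same optimum falls out of exhaustive path enumeration
  expect_equal(brute_dtw(c(0, 0, 1), c(0, 1, 1)), 0)
})

test_that("DTW distance matches the exhaustive path-enumeration oracle", {
  set.seed(1234)
  for (k in 1:200) {
    na <- sample(2:5, 1); nb <- sample(2:5, 1)
    a <- rnorm(na); b <- rnorm(nb)
    step <- sample(c("fewer_delays", "symmetric_weighted"), 1)
    dist <- sample(c("absolute", "squared"), 1)
    al <- dtw_align(a, b, step, dist)
    expect_equal(al$distance, brute_dtw(a, b, step, dist), tolerance = 1e-12)
    # the reported path must attain the reported distance
    expect_equal(path_cost(al$path, a, b, step, dist), al$distance,
                 tolerance = 1e-12)
    expect_valid_path(al$path, na, nb)
  }
})

test_that("DTW distance is symmetric and self-distance is zero", {
  set.seed(99)
  for (k in 1:25) {
    a <- rnorm(sample(3:9, 1)); b <- rnorm(sample(3:9, 1))
    for (step in c("fewer_delays", "symmetric_weighted")) {
      expect_equal(dtw_align(a, b, step)$distance,
                   dtw_align(b, a, step)$distance, tolerance = 1e-12)
    }
    expect_equal(dtw_align(a, a)$distance, 0)
    expect_gte(dtw_align(a, b)$distance, 0)
  }
})

test_that("unequal lengths give boundary-complete paths", {
  set.seed(7)
  al <- dtw_align(rnorm(9), rnorm(12))
  expect_valid_path(al$path, 9L, 12L)
  expect_error(dtw_align(1, c(1, 2)), "at least 2")
})
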