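test_that("a delayed copy of the endpoint outranks noise entities", {
  set.seed(21)
  t <- 12
  ep <- smooth_series(t, seed = 77)
  entities <- rbind(delayed = c(ep[3:t], ep[t] + cumsum(rnorm(2, 0, 0.05))),
                    noise1 = rnorm(t), noise2 = rnorm(t))
  sc <- screen_endpoints(entities, cbind(marker = ep), timepoints = 1:t,
                         n_perm = 99, seed = 5)
  rec <- sc$results$marker$records
  expect_equal(rec$entity[which.min(rec$distance)], "delayed")
  expect_identical(rec$entity, rownames(entities))  # input order preserved
})

test_that("shape mismatches and missing values are rejected up front", {
  ents <- matrix(rnorm(6 * 9), 6, dimnames = list(paste0("g", 1:6), NULL))
  expect_error(screen_endpoints(ents, cbind(e = rnorm(8))), "9")
  expect_error(screen_endpoints(ents, cbind(e = rnorm(9)),
                                timepoints = 1:5), "timepoints")
  bad <- ents; bad[2, 3] <- NA
  expect_error(screen_endpoints(bad, cbind(e = rnorm(9))), "missing")
  expect_error(screen_endpoints(ents, cbind(e = rnorm(9)),
                                out_dirs = c("x", "y")),
               "one output directory")
})

test_that("q_threshold = 1 flags everything and self-screening is perfect", {
  set.seed(31)
  ents <- matrix(rnorm(4 * 9), 4, dimnames = list(paste0("g", 1:4), NULL))
  sc <- screen_endpoints(ents, cbind(e = rnorm(9)), q_threshold = 1,
                         n_perm = 49, seed = 2)
  expect_true(all(sc$results$e$records$significant))

  # entities := endpoints transposed -> each self-pair has distance 0 and
  # the smallest attainable p
  eps <- matrix(rnorm(9 * 2), 9, dimnames = list(NULL, c("e1", "e2")))
  sc2 <- screen_endpoints(t(eps), eps, n_perm = 199, seed = 3)
  for (lab in colnames(eps)) {
    rec <- sc2$results[[lab]]$records
    self <- rec[rec$entity == lab, ]
    expect_equal(self$distance, 0)
    expect_equal(self$p_value, min(rec$p_value))
  }
})

test_that("screens are deterministic given the seed, whatever the row order", {
  set.seed(41)
  ents <- matrix(rnorm(6 * 9), 6, dimnames = list(paste0("g", 1:6), NULL))
  eps <- cbind(m = rnorm(9))
  s1 <- screen_endpoints(ents, eps, n_perm = 99, seed = 7)
  s2 <- screen_endpoints(ents, eps, n_perm = 99, seed = 7)
  expect_identical(s1$results$m$records, s2$results$m$records)
  # per-entity streams hang off labels, so shuffling rows changes nothing
  shuffled <- ents[sample(nrow(ents)), ]
  s3 <- screen_endpoints(shuffled, eps, n_perm = 99, seed = 7)
  strip <- function(r) `rownames<-`(r[order(r$entity), ], NULL)
  expect_identical(strip(s1$results$m$records), strip(s3$results$m$records))
})

test_that("zero-variance entities are dropped with a warning", {
  ents <- rbind(flat = rep(2, 9), ok = rnorm(9))
  expect_warning(sc <- screen_endpoints(ents, cbind(e = rnorm(9)),
                                        n_perm = 19, seed = 1),
                 "zero-variance")
  expect_identical(sc$dropped, "flat")
  expect_identical(sc$results$e$records$entity, "ok")
})

test_that("Pearson arm matches the closed-form correlation", {
  m <- rbind(same = c(1, 5, 2, 8), anti = -c(1, 5, 2, 8),
             probe = c(1, 2, 3, 4))
  ep <- c(1, 2, 3, 5)
  res <- correlate_entities(m, ep, q_threshold = 1)
  # hand-evaluated Pearson formula for the probe row
  dx <- m["probe", ] - mean(m["probe", ]); dy <- ep - mean(ep)
  expect_equal(res$r[res$entity == "probe"],
               sum(dx * dy) / sqrt(sum(dx^2) * sum(dy^2)))
  ex <- correlate_entities(rbind(x = ep, y = -ep), ep, q_threshold = 1)
  expect_equal(ex$r, c(1, -1))
  expect_false(ex$significant_positive[2])  # r < 0 can never count
  expect_true(ex$significant_positive[1])
  expect_warning(correlate_entities(rbind(flat = rep(1, 4), x = ep), ep),
                 "constant")
  expect_error(correlate_entities(m, rep(2, 4)), "constant endpoint")
})

test_that("overlap summaries reproduce printed-count arithmetic", {
  # counts as printed for a menadione cell-cycle endpoint
  ov <- overlap_stats(paste0("d", 1:99),
                      c(paste0("d", 1:13), paste0("c", 1:21)))
  expect_equal(ov$n_dtw, 99); expect_equal(ov$n_corr, 34)
  expect_equal(ov$n_overlap, 13)
  expect_equal(ov$pct_dtw_not_corr, 87)
  expect_equal(ov$pct_corr_found_by_dtw, 38)
  # an empty DTW set leaves its percentage undefined, shown as "–"
  ov0 <- overlap_stats(character(0), paste0("c", 1:5))
  expect_true(is.na(ov0$pct_dtw_not_corr))
  expect_match(paste(capture.output(print(ov0)), collapse = "\n"), "–")
  expect_lte(ov$n_overlap, min(ov$n_corr, ov$n_dtw))
})
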