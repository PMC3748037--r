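# Independent oracles used across the suite.  These deliberately avoid the
# package's own dynamic program: paths are enumerated exhaustively, BH is a
# literal step-up, and permutation nulls are enumerated over all orderings.

# All monotone boundary-complete warp paths between series of lengths n, m
# (steps down/right/diagonal).  Cached: the same grid is reused many times.
.path_cache <- new.env(parent = emptyenv())
enumerate_paths <- function(n, m) {
  key <- paste(n, m)
  if (!is.null(.path_cache[[key]])) return(.path_cache[[key]])
  res <- list()
  recurse <- function(path, i, j) {
    if (i == n && j == m) {
      res[[length(res) + 1L]] <<- do.call(rbind, path)
      return(invisible())
    }
    if (i < n) recurse(c(path, list(c(i + 1L, j))), i + 1L, j)
    if (j < m) recurse(c(path, list(c(i, j + 1L))), i, j + 1L)
    if (i < n && j < m) recurse(c(path, list(c(i + 1L, j + 1L))), i + 1L, j + 1L)
  }
  recurse(list(c(1L, 1L)), 1L, 1L)
  .path_cache[[key]] <- res
  res
}

path_cost <- function(path, a, b, step = "fewer_delays",
                      dist = "absolute") {
  d <- a[path[, 1L]] - b[path[, 2L]]
  d <- if (dist == "absolute") abs(d) else d^2
  if (step == "symmetric_weighted" && nrow(path) > 1L) {
    diag_step <- diff(path[, 1L]) == 1L & diff(path[, 2L]) == 1L
    d <- d * c(1, ifelse(diag_step, 2, 1))
  }
  sum(d)
}

brute_dtw <- function(a, b, step = "fewer_delays", dist = "absolute") {
  min(vapply(enumerate_paths(length(a), length(b)), path_cost, numeric(1),
             a = a, b = b, step = step, dist = dist))
}

# Literal BH step-up: sort ascending, q_(i) = min_{j>=i} p_(j) * m / j.
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- pmin(1, rev(cummin(rev(p[ord] * m / seq_len(m)))))
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# All permutations of 1..n (tiny n only).
all_perms <- function(n) {
  if (n == 1L) return(list(1L))
  out <- list()
  for (p in all_perms(n - 1L))
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# Exact permutation-null exceedance probability for tiny series: the
# fraction of all joint orderings whose DTW distance is <= the observed.
exact_null_fraction <- function(a, b, step = "fewer_delays",
                                dist = "absolute") {
  obs <- brute_dtw(a, b, step, dist)
  pa <- all_perms(length(a)); pb <- all_perms(length(b))
  hits <- 0L; total <- 0L
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    total <- total + 1L
    if (brute_dtw(a[pa[[i]]], b[pb[[j]]], step, dist) <= obs + 1e-12)
      hits <- hits + 1L
  }
  hits / total
}

# Warp-path contract, written independently of the package internals.
expect_valid_path <- function(path, t_a, t_b) {
  expect_true(is.matrix(path) && ncol(path) == 2L)
  expect_equal(unname(path[1L, ]), c(1L, 1L))
  expect_equal(unname(path[nrow(path), ]), c(t_a, t_b))
  di <- diff(path[, 1L]); dj <- diff(path[, 2L])
  expect_true(all(di %in% 0:1 & dj %in% 0:1 & (di + dj) > 0L))
}

rscript_bin <- function() file.path(R.home("bin"), "Rscript")
cli_script <- function() system.file("cli", "warpscreen.R",
                                     package = "warpscreen")
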