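# Deterministic seed derivation -------------------------------------------

# 31-bit polynomial hash of a character key (Lehmer-style modulus). Keeps
# every derived seed strictly below 2^31 so set.seed() always accepts it.
MOD31 <- 2147483647

label_hash <- function(label) {
  codes <- utf8ToInt(as.character(label))
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% MOD31
  h
}

# Mix a run seed with a per-unit key (string label or integer index) into a
# reproducible, iteration-order-independent stream seed.
mix_seed <- function(seed, key) {
  h <- if (is.character(key)) label_hash(key) else as.numeric(key) %% MOD31
  as.integer(((seed %% MOD31) * 48271 + h + 1) %% MOD31)
}

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Permutation null ---------------------------------------------------------

#' Permutation p-value for a DTW distance
#'
#' Estimates how likely a DTW distance at least as small as the observed one
#' is when the temporal ordering carries no information: in each of `n_perm`
#' draws the order of `a`'s values and, separately and independently, the
#' order of `b`'s values are permuted uniformly at random, and the DTW
#' distance of the permuted pair is recorded.  The p-value uses the add-one
#' estimator \eqn{p = (1 + \#\{d_{null} \le d_{obs}\}) / (B + 1)}, which can
#' never return 0 (a permutation p of exactly 0 would invalidate the
#' downstream FDR step) and counts ties against significance.
#'
#' @param a,b Scaled series ([time_series()] or numeric vectors).
#' @param n_perm Number of permutation draws B (>= 1).
#' @param seed Optional integer seed for a self-contained, reproducible
#'   stream; `NULL` uses (and advances) the global RNG.
#' @param step_pattern,local_distance Passed to [dtw_align()].
#' @param swap_invariant If `TRUE`, the two series are put in a canonical
#'   order before the permutation streams are assigned, so the null
#'   distances do not depend on which series is passed first (DTW distance
#'   itself is symmetric).  Used by [screen_matched()].
#' @return List of class `perm_null`: `observed_distance`, `null_distances`
#'   (length B), `p_value` in (0, 1], `n_perm`, and the observed alignment's
#'   `path`.
#' @examples
#' set.seed(1)
#' a <- scale_series(time_series(rnorm(6)))
#' permutation_pvalue(a, a, n_perm = 99, seed = 7)$p_value
#' @export
permutation_pvalue <- function(a, b, n_perm = 1000L, seed = NULL,
                               step_pattern = STEP_PATTERNS,
                               local_distance = LOCAL_DISTANCES,
                               swap_invariant = FALSE) {
  a <- as_time_series(a, "a"); b <- as_time_series(b, "b")
  step_pattern <- match.arg(step_pattern, STEP_PATTERNS)
  local_distance <- match.arg(local_distance, LOCAL_DISTANCES)
  n_perm <- as.integer(n_perm)
  if (n_perm < 1L) stop("n_perm must be >= 1")

  obs <- dtw_align(a, b, step_pattern, local_distance)

  # canonical pair order: permutation stream 1 always goes to the series
  # that sorts first, so swapping the arguments cannot change the null
  x <- a$values; y <- b$values
  if (swap_invariant && series_after(x, y)) { tmp <- x; x <- y; y <- tmp }

  nulls <- with_seed(seed, {
    pa <- t(vapply(seq_len(n_perm), function(k) sample.int(length(x)),
                   integer(length(x))))
    pb <- t(vapply(seq_len(n_perm), function(k) sample.int(length(y)),
                   integer(length(y))))
    cpp_dtw_null(x, y, pa, pb, step_code(step_pattern),
                 dist_code(local_distance))
  })

  # null distances mathematically tied with the observed one can differ in
  # the last bit (different summation order), so ties are counted with a
  # relative tolerance; ties count against significance
  tol <- 1e-9 * (1 + abs(obs$distance))
  structure(list(observed_distance = obs$distance,
                 null_distances = nulls,
                 p_value = (1 + sum(nulls <= obs$distance + tol)) /
                   (n_perm + 1),
                 n_perm = n_perm, path = obs$path),
            class = "perm_null")
}

# TRUE if x sorts strictly after y (length first, then lexicographic).
series_after <- function(x, y) {
  if (length(x) != length(y)) return(length(x) > length(y))
  k <- which(x != y)
  if (!length(k)) return(FALSE)
  x[k[1L]] > y[k[1L]]
}

#' @export
print.perm_null <- function(x, ...) {
  cat("permutation null: observed distance", format(x$observed_distance),
      "| p =", format(x$p_value), "( B =", x$n_perm, ")\n")
  invisible(x)
}

# FDR ----------------------------------------------------------------------

#' Benjamini-Hochberg adjusted p-values
#'
#' Standard step-up FDR adjustment: with sorted p-values \eqn{p_{(1)} \le
#' \dots \le p_{(m)}}, \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped
#' at 1 and mapped back to the input order.  Entities with q at or below the
#' run's threshold are called significant.
#'
#' @param p_values Numeric vector of p-values in (0, 1].
#' @return Numeric vector of q-values, same length and order.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.5))  # 0.04 0.04 0.04 0.50
#' @export
bh_adjust <- function(p_values) {
  if (!length(p_values)) return(numeric(0))
  if (anyNA(p_values) || any(p_values <= 0 | p_values > 1))
    stop("p-values must lie in (0, 1]")
  stats::p.adjust(p_values, method = "BH")
}
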