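STEP_PATTERNS <- c("fewer_delays", "symmetric_weighted")
LOCAL_DISTANCES <- c("absolute", "squared")

step_code <- function(step_pattern) {
  match(match.arg(step_pattern, STEP_PATTERNS), STEP_PATTERNS) - 1L
}
dist_code <- function(local_distance) {
  match(match.arg(local_distance, LOCAL_DISTANCES), LOCAL_DISTANCES) - 1L
}

#' Dynamic time warping alignment of two time courses
#'
#' Computes the minimum accumulated local cost over all monotone,
#' boundary-complete warp paths between two series, by dynamic programming,
#' and returns one optimal path.  Under the default `"fewer_delays"` step
#' pattern the recursion is
#' \deqn{D(i,j) = d(i,j) + \min\{D(i-1,j),\ D(i,j-1),\ D(i-1,j-1)\}}
#' with \eqn{D(1,1) = d(1,1)}: every cell on the path contributes its local
#' cost once, so paths that introduce extra delays (more cells) pay for them.
#' `"symmetric_weighted"` instead counts the local cost of a diagonal step
#' twice (the classic symmetric weighted pattern), removing the preference
#' for diagonal moves.
#'
#' The caller is responsible for scaling both series consistently (see
#' [scale_series()]); lengths may differ.
#'
#' @param a,b [time_series()] objects or numeric vectors.
#' @param step_pattern `"fewer_delays"` (default) or `"symmetric_weighted"`.
#' @param local_distance `"absolute"` (default) or `"squared"` difference.
#' @return An object of class `dtw_alignment`: list with `distance`
#'   (non-negative accumulated cost), `path` (two-column integer matrix of
#'   1-based index pairs from `(1,1)` to `(length(a), length(b))`),
#'   `step_pattern`, `local_distance`, and the two input series.
#' @examples
#' al <- dtw_align(c(0, 0, 1), c(0, 1, 1))
#' al$distance  # 0: the delay absorbs the offset
#' @export
dtw_align <- function(a, b, step_pattern = STEP_PATTERNS,
                      local_distance = LOCAL_DISTANCES) {
  a <- as_time_series(a, "a")
  b <- as_time_series(b, "b")
  step_pattern <- match.arg(step_pattern, STEP_PATTERNS)
  local_distance <- match.arg(local_distance, LOCAL_DISTANCES)
  res <- cpp_dtw(a$values, b$values, step_code(step_pattern),
                 dist_code(local_distance))
  structure(list(distance = res$distance, path = res$path,
                 step_pattern = step_pattern, local_distance = local_distance,
                 a = a, b = b),
            class = "dtw_alignment")
}

#' @export
print.dtw_alignment <- function(x, ...) {
  cat("DTW alignment: '", x$a$label, "' vs '", x$b$label, "'\n", sep = "")
  cat("  distance:", format(x$distance), "(", x$step_pattern, ",",
      x$local_distance, "local distance )\n")
  cat("  path:", paste0("(", x$path[, 1], ",", x$path[, 2], ")",
                        collapse = " "), "\n")
  invisible(x)
}

#' @describeIn dtw_align Plot the alignment: both (scaled) series overlaid
#'   with grey segments joining matched points.
#' @param x A `dtw_alignment`.
#' @param ... Further arguments passed to [graphics::plot()].
#' @export
plot.dtw_alignment <- function(x, ...) {
  plot_warp_panel(x$a, x$b, x$path, ...)
  invisible(x)
}

# Internal check that a path satisfies the warp-path contract:
# starts (1,1), ends (tA,tB), unit steps from {(1,0),(0,1),(1,1)}.
is_valid_warp_path <- function(path, t_a, t_b) {
  if (!is.matrix(path) || ncol(path) != 2L) return(FALSE)
  if (any(path[1L, ] != c(1L, 1L))) return(FALSE)
  if (any(path[nrow(path), ] != c(t_a, t_b))) return(FALSE)
  if (nrow(path) < 2L) return(t_a == 1L && t_b == 1L)
  di <- diff(path[, 1L]); dj <- diff(path[, 2L])
  all(di %in% 0:1 & dj %in% 0:1 & (di + dj) > 0L)
}
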