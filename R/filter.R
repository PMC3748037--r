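#' Pre-filter entities for complete, significant time courses
#'
#' Screening every measured entity is wasteful and statistically costly when
#' many show no temporal response.  This filter first drops rows with any
#' missing value, then keeps a row only if at least one time point deviates
#' from the row's mean by at least `z_threshold` standard deviations, where
#' the mean and the sample (n-1) standard deviation are computed across that
#' row's time points.  The criterion is a z-score, so it is unchanged by
#' rescaling a row; constant rows (sd = 0) are always dropped — they carry
#' no time course and would also break unit-variance scaling downstream.
#'
#' @param x Numeric matrix, entities in rows (unique rownames), time points
#'   in columns (at least 3).  `NA`/`NaN` mark missing values.
#' @param z_threshold Minimum deviation, in row standard deviations, that at
#'   least one time point must reach (default 2).
#' @return List of class `filter_report`: `matrix` (the retained rows, in
#'   original order, no missing values) and counts `n_input`,
#'   `n_dropped_missing`, `n_dropped_flat`, `n_retained`.
#' @examples
#' m <- rbind(spike = c(0, 0, 0, 0, 10, 0, 0, 0, 0),
#'            ramp  = as.numeric(1:9),
#'            holey = c(1, NA, 3, 4, 5, 6, 7, 8, 9))
#' filter_time_courses(m)$matrix  # only the spike survives
#' @export
filter_time_courses <- function(x, z_threshold = 2) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("entity_", seq_len(nrow(x)))
  if (anyDuplicated(rownames(x)))
    stop("duplicate row labels: ",
         paste(unique(rownames(x)[duplicated(rownames(x))]), collapse = ", "))
  if (ncol(x) < 3L)
    stop("need at least 3 time points to assess a time course (got ",
         ncol(x), ")")
  if (!is.numeric(z_threshold) || z_threshold < 0)
    stop("z_threshold must be a non-negative number")

  complete <- !apply(x, 1L, anyNA)
  xc <- x[complete, , drop = FALSE]
  mu <- rowMeans(xc)
  sdv <- apply(xc, 1L, stats::sd)
  maxdev <- apply(abs(xc - mu), 1L, max)
  keep <- sdv > 0 & maxdev >= z_threshold * sdv

  out <- xc[keep, , drop = FALSE]
  if (nrow(out) == 0L)
    warning("no entities passed the time-course filter")
  structure(list(matrix = out,
                 n_input = nrow(x),
                 n_dropped_missing = sum(!complete),
                 n_dropped_flat = sum(!keep),
                 n_retained = nrow(out),
                 z_threshold = z_threshold),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("time-course filter (|z| >=", x$z_threshold, "at >= 1 time point):\n")
  cat("  input entities:    ", x$n_input, "\n")
  cat("  dropped (missing): ", x$n_dropped_missing, "\n")
  cat("  dropped (no significant time course):", x$n_dropped_flat, "\n")
  cat("  retained:          ", x$n_retained, "\n")
  invisible(x)
}
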