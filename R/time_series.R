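#' Construct a labelled time course
#'
#' A `time_series` is a single labelled time course: a numeric vector of
#' measurements and the numeric time points at which they were taken.
#' Time-point values are used for plotting axes; the warping itself operates
#' on index order.
#'
#' @param values Numeric vector of measurements, length >= 2, all finite.
#' @param timepoints Numeric vector of strictly increasing time values, same
#'   length as `values`.  Defaults to `seq_along(values)`.
#' @param label Character scalar identifying the series.
#' @return An object of class `time_series` with fields `label`, `values`,
#'   `timepoints`.
#' @examples
#' ts <- time_series(c(0, 1, 4, 2), label = "g1")
#' @export
time_series <- function(values, timepoints = seq_along(values), label = "") {
  values <- as.numeric(values)
  timepoints <- as.numeric(timepoints)
  if (length(values) < 2L)
    stop("a time series needs at least 2 points (got ", length(values), ")")
  if (length(values) != length(timepoints))
    stop("values (", length(values), ") and timepoints (", length(timepoints),
         ") differ in length")
  if (!all(is.finite(values)))
    stop("non-finite values in series '", label, "'")
  if (any(diff(timepoints) <= 0))
    stop("timepoints must be strictly increasing in series '", label, "'")
  structure(list(label = as.character(label)[1L], values = values,
                 timepoints = timepoints),
            class = "time_series")
}

as_time_series <- function(x, label = "") {
  if (inherits(x, "time_series")) x else time_series(x, label = label)
}

#' @export
print.time_series <- function(x, ...) {
  cat("time_series '", x$label, "' (", length(x$values), " points)\n", sep = "")
  print(rbind(time = x$timepoints, value = x$values))
  invisible(x)
}

#' Scale a time course prior to alignment
#'
#' Series measured on different scales (genes, phenotypic markers) must be
#' rescaled before their DTW distance is meaningful.  `unit_variance`
#' autoscales: it centres the series and divides by the sample (n-1)
#' standard deviation; `mean_center` only centres; `none` is the identity.
#'
#' @param series A [time_series()] or bare numeric vector.
#' @param mode One of `"unit_variance"` (default), `"mean_center"`, `"none"`.
#' @return A `time_series` with the same label and timepoints.
#' @examples
#' scale_series(time_series(c(1, 2, 3)))$values  # -1 0 1
#' @export
scale_series <- function(series,
                         mode = c("unit_variance", "mean_center", "none")) {
  mode <- match.arg(mode)
  s <- as_time_series(series)
  if (mode == "none") return(s)
  v <- s$values - mean(s$values)
  if (mode == "unit_variance") {
    sdv <- stats::sd(s$values)
    if (!is.finite(sdv) || sdv <= 0)
      stop("degenerate series '", s$label,
           "': zero variance, cannot apply unit_variance scaling")
    v <- v / sdv
  }
  s$values <- v
  s
}
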