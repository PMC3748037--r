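#' Generate a smooth random time course
#'
#' Draws `max(4, ceiling(length/5))` knot values iid standard normal at
#' evenly spaced positions spanning `[1, length]`, interpolates them with a
#' cubic spline, and evaluates at the integer positions `1..length`.  The
#' result is smooth (high lag-1 autocorrelation) rather than white noise —
#' the property that makes permutation nulls for real biological series
#' anti-conservative, and the regime the benchmark is built to probe.
#'
#' @param length Number of time points (>= 4).
#' @param seed Optional integer seed; `NULL` uses the global RNG.
#' @return Numeric vector of `length` finite values.
#' @examples
#' plot(smooth_series(20, seed = 1), type = "b")
#' @export
smooth_series <- function(length, seed = NULL) {
  length <- as.integer(length)
  if (length < 4L) stop("length must be >= 4 (got ", length, ")")
  with_seed(seed, {
    k <- max(4L, ceiling(length / 5))
    xk <- seq(1, length, length.out = k)
    yk <- stats::rnorm(k)
    stats::spline(xk, yk, xout = seq_len(length), method = "fmm")$y
  })
}

#' Build the shift-and-noise matched-screen benchmark
#'
#' Generates two matched entity sets with known ground truth.  For each of
#' `n_matched` matched rows a smooth "mother" series of length
#' `length + max_shift` is drawn; set A gets its first `length` points, set
#' B gets the window starting `shift` points later plus iid Gaussian noise
#' with standard deviation `multiplier * sd(mother)`.  Shifts `0..max_shift`
#' and the noise ladder are crossed in equal-sized cells (round-robin
#' assignment).  A further `n_decoys` rows of both sets are independent
#' smooth series sharing a label, so they are screened but carry no true
#' match.  With the defaults this reproduces the canonical configuration:
#' 11,000 rows per set (10,000 matched + 1,000 decoys), series of length
#' 20, shifts 0-9, 10 noise levels at 10\%..100\% of signal sd.
#'
#' @param n_matched Matched rows (default 10000); truncated with a warning
#'   to the largest multiple of the number of (shift, noise) cells.
#' @param n_decoys Unmatched decoy rows (default 1000).
#' @param length Series length L (default 20).
#' @param max_shift Largest time shift in grid units (default 9).
#' @param n_noise_levels Number of noise levels (default 10).
#' @param noise_step Noise-ladder increment as a fraction of the mother
#'   series' sd (default 0.1, so levels run 0.1..1.0 x sd).
#' @param noise_multipliers Optional explicit multiplier ladder overriding
#'   `n_noise_levels`/`noise_step` (e.g. include 0 for a zero-corruption
#'   level).
#' @param seed Integer seed; the whole benchmark is reproducible from it.
#' @return Object of class `dtw_benchmark`: matrices `setA`, `setB` (shared
#'   rownames), `truth` data frame (label, matched, shift, noise_level,
#'   noise_sd), `length`, `mother_length`, `noise_multipliers`.
#' @examples
#' bm <- make_benchmark(n_matched = 100, n_decoys = 10, seed = 1)
#' table(bm$truth$shift, bm$truth$noise_level)
#' @export
make_benchmark <- function(n_matched = 10000L, n_decoys = 1000L,
                           length = 20L, max_shift = 9L,
                           n_noise_levels = 10L, noise_step = 0.1,
                           noise_multipliers = NULL, seed = 1L) {
  length <- as.integer(length); max_shift <- as.integer(max_shift)
  if (max_shift < 0L || max_shift >= length)
    stop("max_shift must lie in [0, length)")
  if (is.null(noise_multipliers))
    noise_multipliers <- noise_step * seq_len(n_noise_levels)
  n_noise_levels <- base::length(noise_multipliers)
  n_cells <- (max_shift + 1L) * n_noise_levels
  per_cell <- n_matched %/% n_cells
  if (per_cell < 1L)
    stop("n_matched (", n_matched, ") smaller than the number of (shift, ",
         "noise) cells (", n_cells, ")")
  if (n_matched %% n_cells != 0L) {
    warning("n_matched truncated from ", n_matched, " to ",
            per_cell * n_cells, " for balanced cells")
    n_matched <- per_cell * n_cells
  }
  mother_length <- length + max_shift

  cells <- expand.grid(shift = 0:max_shift, noise_level = seq_len(n_noise_levels))
  idx <- rep(seq_len(n_cells), length.out = n_matched)  # round-robin

  n_total <- n_matched + n_decoys
  labels <- sprintf("e%05d", seq_len(n_total))
  setA <- matrix(NA_real_, n_total, length, dimnames = list(labels, NULL))
  setB <- matrix(NA_real_, n_total, length, dimnames = list(labels, NULL))
  shift <- noise_level <- rep(NA_integer_, n_total)
  noise_sd <- rep(NA_real_, n_total)

  with_seed(seed, {
    for (i in seq_len(n_matched)) {
      k <- cells$shift[idx[i]]
      lev <- cells$noise_level[idx[i]]
      mother <- smooth_series(mother_length)
      sdn <- noise_multipliers[lev] * stats::sd(mother)
      setA[i, ] <- mother[seq_len(length)]
      setB[i, ] <- mother[(1 + k):(length + k)] +
        if (sdn > 0) stats::rnorm(length, 0, sdn) else 0
      shift[i] <- k; noise_level[i] <- lev; noise_sd[i] <- sdn
    }
    for (i in seq.int(n_matched + 1L, length.out = n_decoys)) {
      setA[i, ] <- smooth_series(length)
      setB[i, ] <- smooth_series(length)
    }
  })

  truth <- data.frame(label = labels,
                      matched = c(rep(TRUE, n_matched), rep(FALSE, n_decoys)),
                      shift = shift, noise_level = noise_level,
                      noise_sd = noise_sd, stringsAsFactors = FALSE)
  structure(list(setA = setA, setB = setB, truth = truth, length = length,
                 mother_length = mother_length,
                 noise_multipliers = noise_multipliers,
                 seed = as.integer(seed)),
            class = "dtw_benchmark")
}

#' @export
print.dtw_benchmark <- function(x, ...) {
  cat("matched-DTW benchmark:", nrow(x$setA), "rows per set, length",
      x$length, "\n")
  cat("  matched:", sum(x$truth$matched), "| decoys:", sum(!x$truth$matched),
      "\n")
  cat("  shifts 0-", max(x$truth$shift, na.rm = TRUE), ", noise multipliers ",
      paste(format(x$noise_multipliers), collapse = " "), "\n", sep = "")
  invisible(x)
}

#' Ground-truth warp path for a pure time shift
#'
#' The path that aligns `A[i]` with `B[i - shift]` over the overlap of a
#' pair built by windowing the same mother series `shift` points apart:
#' B is held at its first point while A catches up — `(i, 1)` for
#' `i = 1..shift+1` — then the path runs diagonally to `(L, L - shift)` and
#' finally A is held at its last point — `(L, j)` for
#' `j = L-shift+1 .. L`.  Shift 0 gives the pure diagonal.
#'
#' @param length Series length L.
#' @param shift Time shift in grid units, `0 <= shift < length`.
#' @return Two-column integer matrix of 1-based index pairs.
#' @examples
#' intended_path(5, 2)
#' @export
intended_path <- function(length, shift) {
  length <- as.integer(length); shift <- as.integer(shift)
  if (shift < 0L || shift >= length)
    stop("shift must lie in [0, length)")
  i <- c(seq_len(shift + 1L),                        # hold B at its start
         seq.int(shift + 2L, length.out = length - shift - 1L),
         rep(length, shift))                         # hold A at its end
  j <- c(rep(1L, shift + 1L),
         seq.int(2L, length.out = length - shift - 1L),
         seq.int(length - shift + 1L, length.out = shift))
  cbind(i, j, deparse.level = 0)
}

#' Score a matched screen against benchmark ground truth
#'
#' Fills the two evaluation grids: for every (noise level, shift) cell, the
#' percentage of truly matched pairs flagged significant at `fdr`, and the
#' percentage whose returned warp path is literally identical to
#' [intended_path()] for that cell's shift (a co-optimal alternative path
#' counts as a miss).  Decoy detection — the percentage of unmatched smooth
#' pairs flagged significant — is reported alongside; for smooth series it
#' typically exceeds the nominal rate, the known optimism of permutation
#' nulls on smooth data.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param screen The [screen_matched()] result over the benchmark's labels.
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @return Object of class `benchmark_evaluation`: `detection_pct` and
#'   `exact_path_pct` (noise-level x shift matrices, percentages),
#'   `decoy_detection_pct`, `n_per_cell`, `fdr`.
#' @export
evaluate_benchmark <- function(benchmark, screen, fdr = 0.05) {
  stopifnot(inherits(benchmark, "dtw_benchmark"))
  records <- screen$records
  paths <- screen$paths
  truth <- benchmark$truth
  if (!all(truth$label %in% records$entity))
    stop("screen records do not cover all benchmark labels")
  ord <- match(truth$label, records$entity)
  sig <- records$q_value[ord] <= fdr
  paths <- paths[ord]

  shifts <- sort(unique(truth$shift[truth$matched]))
  levels <- sort(unique(truth$noise_level[truth$matched]))
  det <- ex <- matrix(NA_real_, length(levels), length(shifts),
                      dimnames = list(noise_level = levels, shift = shifts))
  npc <- NA_integer_
  for (a in seq_along(levels)) for (s in seq_along(shifts)) {
    in_cell <- which(truth$matched & truth$shift == shifts[s] &
                       truth$noise_level == levels[a])
    npc <- length(in_cell)
    det[a, s] <- 100 * mean(sig[in_cell])
    ipath <- intended_path(benchmark$length, shifts[s])
    ex[a, s] <- 100 * mean(vapply(in_cell, function(i)
      identical(dim(paths[[i]]), dim(ipath)) && all(paths[[i]] == ipath),
      logical(1)))
  }
  decoy <- 100 * mean(sig[!truth$matched])
  structure(list(detection_pct = det, exact_path_pct = ex,
                 decoy_detection_pct = decoy, n_per_cell = npc, fdr = fdr),
            class = "benchmark_evaluation")
}

#' @export
print.benchmark_evaluation <- function(x, ...) {
  cat("benchmark evaluation at FDR", format(x$fdr), "(", x$n_per_cell,
      "pairs per cell )\n")
  cat("detection % (rows: noise level, cols: shift):\n")
  print(round(x$detection_pct, 1))
  cat("exact shift-pattern recovery %:\n")
  print(round(x$exact_path_pct, 1))
  cat("decoy detection %:", format(round(x$decoy_detection_pct, 2)), "\n")
  invisible(x)
}

#' @describeIn evaluate_benchmark Heat-map panels of the two grids (shift on
#'   the x-axis, noise level on the y-axis, low noise at the top).
#' @param x A `benchmark_evaluation`.
#' @param ... Ignored.
#' @export
plot.benchmark_evaluation <- function(x, ...) {
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(old))
  draw_grid <- function(m, main) {
    nl <- nrow(m); ns <- ncol(m)
    image(x = as.numeric(colnames(m)), y = seq_len(nl),
          z = t(m[nl:1, , drop = FALSE]), zlim = c(0, 100),
          col = grDevices::hcl.colors(64, "YlOrRd", rev = TRUE),
          xlab = "time shift (units)", ylab = "", axes = FALSE, main = main)
    axis(1, at = as.numeric(colnames(m)))
    axis(2, at = seq_len(nl), labels = rev(rownames(m)), las = 1)
    mtext("noise level (low at top)", side = 2, line = 2.5)
  }
  draw_grid(x$detection_pct, sprintf("%% detected (FDR %s)", format(x$fdr)))
  draw_grid(x$exact_path_pct, "% exact shift pattern")
  invisible(x)
}

#' @importFrom graphics image
NULL
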