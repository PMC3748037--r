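MISSING_TOKENS <- c("", "NA", "NaN", "nan")

#' Read a labelled numeric matrix from TSV
#'
#' The matrix dialect used throughout: tab-separated, a header row of
#' column labels (time points or endpoints, with an optional empty leading
#' cell), and a first column of row labels.  Empty cells and the tokens
#' `NA`/`NaN` are read as missing.
#'
#' @param path Path to a TSV file.
#' @param orientation `"entities_by_time"` (n x t, rows are entities) or
#'   `"time_by_endpoints"` (t x e, rows are time points).
#' @return Numeric matrix with dimnames.  Ragged
#'   rows, non-numeric cells and duplicate row labels raise parse errors
#'   naming the offending line.
#' @export
read_matrix <- function(path,
                        orientation = c("entities_by_time",
                                        "time_by_endpoints")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) < 2L) stop("parse error in ", path, ": no data rows")
  cells <- strsplit(lines, "\t", fixed = TRUE)
  header <- cells[[1L]]
  if (header[1L] == "") header <- header[-1L]  # optional empty corner cell
  ncols <- length(header)
  body <- cells[-1L]
  vals <- matrix(NA_real_, length(body), ncols)
  labs <- character(length(body))
  for (k in seq_along(body)) {
    row <- body[[k]]
    if (length(row) != ncols + 1L)
      stop("parse error in ", path, " line ", k + 1L, ": expected ",
           ncols + 1L, " fields, found ", length(row))
    labs[k] <- row[1L]
    x <- row[-1L]
    x[x %in% MISSING_TOKENS] <- NA
    num <- suppressWarnings(as.numeric(x))
    bad <- which(is.na(num) & !is.na(x))
    if (length(bad))
      stop("parse error in ", path, " line ", k + 1L,
           ": non-numeric cell '", x[bad[1L]], "'")
    vals[k, ] <- num
  }
  if (anyDuplicated(labs))
    stop("parse error in ", path, ": duplicate row label '",
         labs[duplicated(labs)][1L], "'")
  dimnames(vals) <- list(labs, header)
  vals
}

#' Write a labelled numeric matrix as TSV
#'
#' Inverse of [read_matrix()]: values are written with full (17 significant
#' digit) precision so a write/read round trip reproduces them bit for bit.
#'
#' @param x Numeric matrix with rownames (colnames optional).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(x, path) {
  x <- as.matrix(x)
  if (is.null(rownames(x))) rownames(x) <- paste0("row_", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("c", seq_len(ncol(x)))
  chr <- matrix(sprintf("%.17g", x), nrow(x))
  chr[is.na(x)] <- "NA"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("", colnames(x)), collapse = "\t"), con)
  writeLines(paste(rownames(x), apply(chr, 1L, paste, collapse = "\t"),
                   sep = "\t"), con)
  invisible(path)
}

#' Write a benchmark set as plain-text files
#'
#' Writes `setA.tsv`, `setB.tsv` (entity matrices) and `truth.tsv` (the
#' ground-truth table) into a directory.
#'
#' @param benchmark A [make_benchmark()] object.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark <- function(benchmark, dir) {
  stopifnot(inherits(benchmark, "dtw_benchmark"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(benchmark$setA, file.path(dir, "setA.tsv"))
  write_matrix(benchmark$setB, file.path(dir, "setB.tsv"))
  utils::write.table(benchmark$truth, file.path(dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a benchmark truth table written by [write_benchmark()]
#' @param path Path to `truth.tsv`.
#' @return Data frame with columns label, matched, shift, noise_level,
#'   noise_sd.
#' @export
read_truth <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write an evaluation grid as TSV plus heat-map images
#'
#' @param evaluation A [evaluate_benchmark()] result.
#' @param dir Output directory (created if needed).
#' @param image_format `"jpeg"` (default) or `"png"`.
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(evaluation, dir,
                             image_format = c("jpeg", "png")) {
  stopifnot(inherits(evaluation, "benchmark_evaluation"))
  image_format <- match.arg(image_format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_matrix(evaluation$detection_pct, file.path(dir, "detection_pct.tsv"))
  write_matrix(evaluation$exact_path_pct,
               file.path(dir, "exact_path_pct.tsv"))
  writeLines(sprintf("decoy_detection_pct\t%.17g",
                     evaluation$decoy_detection_pct),
             file.path(dir, "decoy_detection_pct.tsv"))
  open_device(file.path(dir, paste0("evaluation_grids.", ext(image_format))),
              image_format, width = 1200, height = 550)
  plot(evaluation)
  grDevices::dev.off()
  invisible(dir)
}
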