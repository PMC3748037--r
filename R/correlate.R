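#' Pearson-correlation screen of entities against one endpoint
#'
#' The standard alternative to a DTW screen: Pearson correlation of each
#' entity row with the endpoint across the shared time points, a two-sided
#' p-value from the usual t-distribution test of r, BH correction across
#' the entities, and a positive-significance flag (q at or below the
#' threshold AND r > 0).  Correlation only detects time courses that run in
#' parallel; comparing its hits with a DTW screen ([overlap_stats()]) shows
#' how many associations are delayed rather than simultaneous.
#'
#' @param entities Numeric n x t matrix with unique rownames, no missing
#'   values.
#' @param endpoint Numeric vector of length t (or a [time_series()]).
#' @param q_threshold Significance threshold on the BH q-value (default
#'   0.05).
#' @return Data frame with columns entity, r, p_value, q_value,
#'   significant_positive.  Constant entities (undefined r) are excluded
#'   with a warning.
#' @examples
#' m <- rbind(up = 1:5, down = 5:1)
#' correlate_entities(m, 1:5)
#' @export
correlate_entities <- function(entities, endpoint, q_threshold = 0.05) {
  entities <- as.matrix(entities)
  ep <- if (inherits(endpoint, "time_series")) endpoint$values
        else as.numeric(endpoint)
  if (ncol(entities) != length(ep))
    stop("entities have ", ncol(entities), " time points but endpoint has ",
         length(ep))
  if (stats::sd(ep) == 0) stop("constant endpoint: correlation undefined")
  if (is.null(rownames(entities)))
    rownames(entities) <- paste0("entity_", seq_len(nrow(entities)))

  sds <- apply(entities, 1L, stats::sd)
  if (any(sds == 0)) {
    warning("excluding ", sum(sds == 0),
            " constant entities with undefined correlation")
    entities <- entities[sds > 0, , drop = FALSE]
  }
  tests <- apply(entities, 1L, function(row)
    stats::cor.test(row, ep, method = "pearson", alternative = "two.sided"))
  r <- vapply(tests, function(tt) unname(tt$estimate), numeric(1))
  # a perfect correlation gives p = 0 exactly; clamp so BH stays defined
  p <- pmax(vapply(tests, function(tt) tt$p.value, numeric(1)),
            .Machine$double.xmin)
  q <- bh_adjust(p)
  data.frame(entity = rownames(entities), r = r, p_value = p, q_value = q,
             significant_positive = q <= q_threshold & r > 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

# round half away from zero, for report parity with printed percentages
round_half_away <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Overlap between DTW-significant and correlation-significant entities
#'
#' Summarises how a DTW screen's hits relate to a positive-correlation
#' screen's hits for one endpoint: the two counts, their overlap, the
#' percentage of DTW hits not found by correlation, and the percentage of
#' correlation hits that DTW also found.  Percentages are rounded to the
#' nearest integer (half away from zero); a percentage whose denominator is
#' zero is undefined and printed as "–".
#'
#' @param dtw_significant Character vector of DTW-significant entity labels.
#' @param corr_significant_positive Character vector of entity labels with
#'   significant positive correlation.
#' @param endpoint Optional endpoint label for display.
#' @return Object of class `overlap_summary`: `endpoint`, `n_corr`, `n_dtw`,
#'   `n_overlap`, `pct_dtw_not_corr`, `pct_corr_found_by_dtw` (the two
#'   percentages are `NA` when undefined).
#' @examples
#' overlap_stats(paste0("g", 1:99), paste0("g", 87:120))
#' @export
overlap_stats <- function(dtw_significant, corr_significant_positive,
                          endpoint = "") {
  dtw_significant <- unique(as.character(dtw_significant))
  corr_significant_positive <- unique(as.character(corr_significant_positive))
  n_dtw <- length(dtw_significant)
  n_corr <- length(corr_significant_positive)
  n_overlap <- length(intersect(dtw_significant, corr_significant_positive))
  pct1 <- if (n_dtw > 0) round_half_away(100 * (n_dtw - n_overlap) / n_dtw)
          else NA_real_
  pct2 <- if (n_corr > 0) round_half_away(100 * n_overlap / n_corr)
          else NA_real_
  structure(list(endpoint = endpoint, n_corr = n_corr, n_dtw = n_dtw,
                 n_overlap = n_overlap, pct_dtw_not_corr = pct1,
                 pct_corr_found_by_dtw = pct2),
            class = "overlap_summary")
}

fmt_pct <- function(x) if (is.na(x)) "–" else paste0(x, "%")

#' @export
print.overlap_summary <- function(x, ...) {
  if (nzchar(x$endpoint)) cat("endpoint:", x$endpoint, "\n")
  cat("  positive-correlation entities:", x$n_corr, "\n")
  cat("  DTW entities:                 ", x$n_dtw, "\n")
  cat("  overlap:                      ", x$n_overlap, "\n")
  cat("  DTW entities not found by correlation:", fmt_pct(x$pct_dtw_not_corr),
      "\n")
  cat("  correlation entities found by DTW:    ",
      fmt_pct(x$pct_corr_found_by_dtw), "\n")
  invisible(x)
}
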