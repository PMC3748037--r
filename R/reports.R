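ext <- function(image_format) if (image_format == "jpeg") "jpg" else "png"

open_device <- function(path, image_format, width = 900, height = 450) {
  if (image_format == "jpeg")
    grDevices::jpeg(path, width = width, height = height, quality = 90)
  else
    grDevices::png(path, width = width, height = height)
}

# One warped-alignment panel: both scaled series with matched points joined.
plot_warp_panel <- function(a, b, path, main = "warped alignment", ...) {
  xa <- a$timepoints[path[, 1L]]
  xb <- b$timepoints[path[, 2L]]
  ya <- a$values[path[, 1L]]
  yb <- b$values[path[, 2L]]
  plot(range(c(a$timepoints, b$timepoints)), range(c(ya, yb)), type = "n",
       xlab = "time", ylab = "scaled value", main = main, ...)
  segments(xa, ya, xb, yb, col = "grey70")
  lines(a$timepoints, a$values, type = "b", col = "firebrick", pch = 16)
  lines(b$timepoints, b$values, type = "b", col = "navy", pch = 17)
  legend("topleft", bty = "n", lty = 1, pch = c(16, 17),
         col = c("firebrick", "navy"),
         legend = c(a$label, b$label), cex = 0.8)
}

# Before/after warping figure for one entity-endpoint (or matched) pair.
warp_figure <- function(a, b, path, title) {
  old <- par(mfrow = c(1, 2), mar = c(4, 4, 3, 1))
  on.exit(par(old))
  plot(range(c(a$timepoints, b$timepoints)),
       range(c(a$values, b$values)), type = "n", xlab = "time",
       ylab = "scaled value", main = paste(title, "- original"))
  lines(a$timepoints, a$values, type = "b", col = "firebrick", pch = 16)
  lines(b$timepoints, b$values, type = "b", col = "navy", pch = 17)
  legend("topleft", bty = "n", lty = 1, pch = c(16, 17),
         col = c("firebrick", "navy"), legend = c(a$label, b$label),
         cex = 0.8)
  plot_warp_panel(a, b, path, main = paste(title, "- warped"))
}

null_overlay_histogram <- function(observed, nulls, main) {
  brk <- pretty(c(observed, nulls), n = 30)
  hn <- hist(nulls, breaks = brk, plot = FALSE)
  ho <- hist(observed, breaks = brk, plot = FALSE)
  plot(hn, col = grDevices::adjustcolor("grey40", 0.6), border = NA,
       freq = FALSE, main = main, xlab = "DTW distance")
  plot(ho, col = grDevices::adjustcolor("firebrick", 0.6), border = NA,
       freq = FALSE, add = TRUE)
  legend("topright", bty = "n", fill = c("grey40", "firebrick"),
         legend = c("permuted", "observed"))
}

best_entity_histogram <- function(nulls, observed, label) {
  hist(nulls, breaks = 30, col = "grey80", border = "white",
       main = paste("permutation null:", label),
       xlab = "DTW distance")
  points(observed, 0, pch = 4, cex = 3, lwd = 3, col = "firebrick")
  text(observed, 0, "observed", pos = 3, col = "firebrick")
}

run_summary_lines <- function(result, dropped = character()) {
  p <- result$params
  records <- result$records
  best <- best_record(records)
  c(paste0("function: ", p$function_name),
    if (!is.null(result$endpoint)) paste0("endpoint: ", result$endpoint),
    paste0("scaling: ", p$scaling),
    paste0("step_pattern: ", p$step_pattern),
    paste0("local_distance: ", p$local_distance),
    paste0("n_perm: ", p$n_perm),
    paste0("seed: ", p$seed),
    paste0("q_threshold: ", format(p$q_threshold)),
    paste0("n_entities: ", nrow(records)),
    paste0("n_significant: ", sum(records$significant)),
    if (length(dropped))
      paste0("dropped_zero_variance: ", paste(dropped, collapse = ",")),
    if (!is.null(result$unpaired_a))
      paste0("unpaired_in_A: ", length(result$unpaired_a)),
    if (!is.null(result$unpaired_b))
      paste0("unpaired_in_B: ", length(result$unpaired_b)),
    "# most significant entity (reported regardless of the q threshold)",
    paste0("best_entity: ", best$entity),
    paste0("best_distance: ", format(best$distance, digits = 15)),
    paste0("best_p: ", format(best$p_value, digits = 15)),
    paste0("best_q: ", format(best$q_value, digits = 15)))
}

#' Write the report files and plots for one screen
#'
#' Writes, into `out_dir`: `significant_entities.txt` (one line per
#' significant entity — label, distance, p, q — sorted by q, then p, then
#' label; empty when none is significant), `run_summary.txt` (all run
#' parameters plus the most significant entity, reported whether or not it
#' reached the q threshold), one `<entity>_warp.<ext>` before/after warp
#' figure per significant entity, `null_histogram.<ext>` (observed
#' distances overlaid on pooled permuted distances), and
#' `best_entity_null.<ext>` (the most significant entity's permutation null
#' with the observed distance marked by an X).
#'
#' @param result A per-endpoint `screen_result` (from [screen_endpoints()])
#'   or a [screen_matched()] object.
#' @param out_dir Output directory (created if needed).
#' @param image_format `"jpeg"` (default) or `"png"`.
#' @param dropped Labels dropped before screening, echoed in the summary.
#' @return Character vector of the files written, invisibly.
#' @export
write_screen_outputs <- function(result, out_dir,
                                 image_format = c("jpeg", "png"),
                                 dropped = character()) {
  image_format <- match.arg(image_format)
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", out_dir)
  records <- result$records
  matched <- inherits(result, "matched_screen")
  e <- ext(image_format)
  written <- character(0)

  sig <- records[records$significant, , drop = FALSE]
  sig <- sig[order(sig$q_value, sig$p_value, sig$entity), , drop = FALSE]
  sig_path <- file.path(out_dir, "significant_entities.txt")
  writeLines(sprintf("%s\t%.15g\t%.15g\t%.15g", sig$entity, sig$distance,
                     sig$p_value, sig$q_value), sig_path)
  written <- c(written, sig_path)

  sum_path <- file.path(out_dir, "run_summary.txt")
  writeLines(run_summary_lines(result, dropped), sum_path)
  written <- c(written, sum_path)

  pair_of <- function(lab) {
    if (matched) list(a = result$series_a[[lab]], b = result$series_b[[lab]])
    else list(a = result$series[[lab]], b = result$endpoint_series)
  }
  for (lab in sig$entity) {
    k <- match(lab, records$entity)
    f <- file.path(out_dir, paste0(lab, "_warp.", e))
    open_device(f, image_format)
    pr <- pair_of(lab)
    warp_figure(pr$a, pr$b, result$paths[[k]], lab)
    grDevices::dev.off()
    written <- c(written, f)
  }

  f <- file.path(out_dir, paste0("null_histogram.", e))
  open_device(f, image_format)
  null_overlay_histogram(records$distance, unlist(result$nulls),
                         "observed vs permuted DTW distances")
  grDevices::dev.off()
  written <- c(written, f)

  best <- best_record(records)
  k <- match(best$entity, records$entity)
  f <- file.path(out_dir, paste0("best_entity_null.", e))
  open_device(f, image_format)
  best_entity_histogram(result$nulls[[k]], best$distance, best$entity)
  grDevices::dev.off()
  written <- c(written, f)

  invisible(written)
}
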