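#' Screen every entity against every endpoint by DTW
#'
#' The primary screen.  For each endpoint (column of `endpoints`), every
#' entity (row of `entities`) is scaled, aligned to the scaled endpoint by
#' [dtw_align()], and assigned a permutation p-value ([permutation_pvalue()]
#' with each series' temporal order permuted separately per draw).
#' Benjamini-Hochberg correction is then applied across the entities within
#' each endpoint, and entities with q-value at or below `q_threshold` are
#' flagged significant.
#'
#' Entities should be pre-filtered ([filter_time_courses()]); rows with zero
#' variance cannot be unit-variance scaled and are dropped with a warning.
#' Each entity gets a deterministic permutation stream derived from `seed`
#' and its label (and the endpoint's label), so results are reproducible and
#' independent of row order.
#'
#' @param entities Numeric n x t matrix, unique rownames, no missing values.
#' @param endpoints Numeric t x e matrix of endpoint time courses, one per
#'   column (colnames used as labels); `t` must match `entities`.
#' @param timepoints Numeric vector of the t time values (plot axes only).
#' @param out_dirs Optional character vector, one writable directory per
#'   endpoint: per-endpoint report files and plots are written there (see
#'   [write_screen_outputs()]).  `NULL` (default) skips all file output.
#' @param scaling Per-series scaling applied before DTW (default
#'   `"unit_variance"`); see [scale_series()].
#' @param q_threshold Maximum q-value for an entity to be significant
#'   (default 0.05; consider 0.01 for long, smooth series, whose permutation
#'   p-values tend to overstate significance).
#' @param n_perm Permutation draws per entity (default 1000).
#' @param seed Integer run seed driving all permutation streams.
#' @param step_pattern,local_distance Passed to [dtw_align()].
#' @param image_format `"jpeg"` (default) or `"png"` for the plot files.
#' @return Object of class `endpoint_screen`: list with `results` (one
#'   `screen_result` per endpoint, each holding a `records` data frame with
#'   columns entity, distance, p_value, q_value, significant, plus warp
#'   paths and null distances), `dropped` (labels dropped for zero
#'   variance), and `params`.
#' @examples
#' set.seed(42)
#' ents <- matrix(rnorm(5 * 9), 5, dimnames = list(paste0("g", 1:5), NULL))
#' eps <- cbind(time = 1:9)
#' sc <- screen_endpoints(ents, eps, timepoints = 1:9, n_perm = 49, seed = 1)
#' summary(sc)
#' @export
screen_endpoints <- function(entities, endpoints, timepoints = NULL,
                             out_dirs = NULL,
                             scaling = c("unit_variance", "mean_center", "none"),
                             q_threshold = 0.05, n_perm = 1000L, seed = 1L,
                             step_pattern = STEP_PATTERNS,
                             local_distance = LOCAL_DISTANCES,
                             image_format = c("jpeg", "png")) {
  scaling <- match.arg(scaling)
  step_pattern <- match.arg(step_pattern, STEP_PATTERNS)
  local_distance <- match.arg(local_distance, LOCAL_DISTANCES)
  image_format <- match.arg(image_format)
  entities <- as.matrix(entities)
  endpoints <- as.matrix(endpoints)
  if (ncol(entities) != nrow(endpoints))
    stop("entity matrix is ", nrow(entities), "x", ncol(entities),
         " but endpoint matrix is ", nrow(endpoints), "x", ncol(endpoints),
         ": time-point dimensions disagree")
  if (is.null(timepoints)) timepoints <- seq_len(ncol(entities))
  if (length(timepoints) != ncol(entities))
    stop("timepoints has length ", length(timepoints), ", expected ",
         ncol(entities))
  if (is.null(rownames(entities)))
    rownames(entities) <- paste0("entity_", seq_len(nrow(entities)))
  if (anyDuplicated(rownames(entities)))
    stop("duplicate entity labels")
  if (is.null(colnames(endpoints)))
    colnames(endpoints) <- paste0("endpoint_", seq_len(ncol(endpoints)))
  if (!is.null(out_dirs) && length(out_dirs) != ncol(endpoints))
    stop("need one output directory per endpoint (", ncol(endpoints),
         "), got ", length(out_dirs))
  if (anyNA(entities) || anyNA(endpoints))
    stop("missing values present; run filter_time_courses() first")

  dropped <- character(0)
  if (scaling == "unit_variance") {
    sds <- apply(entities, 1L, stats::sd)
    dropped <- rownames(entities)[sds == 0]
    if (length(dropped)) {
      warning("dropping ", length(dropped),
              " zero-variance entities: cannot unit-variance scale (",
              paste(utils::head(dropped, 5L), collapse = ", "),
              if (length(dropped) > 5L) ", ..." else "", ")")
      entities <- entities[sds > 0, , drop = FALSE]
    }
    if (any(apply(endpoints, 2L, stats::sd) == 0))
      stop("zero-variance endpoint cannot be unit-variance scaled")
  }
  if (nrow(entities) == 0L) stop("no entities left to screen")

  params <- list(function_name = "screen_endpoints", scaling = scaling,
                 q_threshold = q_threshold, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), step_pattern = step_pattern,
                 local_distance = local_distance,
                 n_entities = nrow(entities), n_endpoints = ncol(endpoints))

  labels <- rownames(entities)
  ent_scaled <- lapply(labels, function(lab)
    scale_series(time_series(entities[lab, ], timepoints, lab), scaling))
  names(ent_scaled) <- labels

  results <- lapply(colnames(endpoints), function(ep_lab) {
    ep <- scale_series(time_series(endpoints[, ep_lab], timepoints, ep_lab),
                       scaling)
    ep_seed <- mix_seed(seed, ep_lab)
    pns <- lapply(labels, function(lab)
      permutation_pvalue(ent_scaled[[lab]], ep, n_perm,
                         seed = mix_seed(ep_seed, lab),
                         step_pattern = step_pattern,
                         local_distance = local_distance))
    p <- vapply(pns, `[[`, numeric(1), "p_value")
    q <- bh_adjust(p)
    records <- data.frame(entity = labels,
                          distance = vapply(pns, `[[`, numeric(1),
                                            "observed_distance"),
                          p_value = p, q_value = q,
                          significant = q <= q_threshold,
                          row.names = NULL, stringsAsFactors = FALSE)
    structure(list(endpoint = ep_lab, records = records,
                   paths = lapply(pns, `[[`, "path"),
                   nulls = lapply(pns, `[[`, "null_distances"),
                   series = ent_scaled, endpoint_series = ep,
                   timepoints = timepoints, params = params),
              class = "screen_result")
  })
  names(results) <- colnames(endpoints)

  out <- structure(list(results = results, dropped = dropped,
                        params = params),
                   class = "endpoint_screen")
  if (!is.null(out_dirs))
    for (j in seq_along(results))
      write_screen_outputs(results[[j]], out_dirs[j], image_format,
                           dropped = dropped)
  out
}

#' Compare the same entities measured in two experiments
#'
#' Matched DTW: the same labelled entity measured under two conditions (or
#' in two systems) is expected to show the same response, possibly with
#' different delays.  Rows are paired by label; only the intersection of the
#' two sets of row labels is analysed, and the time grids may differ in both
#' values and length.  Each pair is scaled, aligned, and assigned a
#' permutation p-value; BH correction runs across the label intersection.
#'
#' Each label's permutation stream is derived from `seed` and the label, and
#' the pair is put in a canonical internal order before the streams are
#' assigned, so swapping `a` and `b` changes neither p-values nor the set of
#' significant labels (DTW distance is symmetric).
#'
#' @param a,b Numeric entity matrices (n1 x t1 and n2 x t2) with unique
#'   rownames; t1 and t2 may differ.
#' @param timepoints_a,timepoints_b Optional time values for the two grids.
#' @param out_dir Optional writable directory for report files and plots.
#' @inheritParams screen_endpoints
#' @return Object of class `matched_screen`: `records` data frame (entity,
#'   distance, p_value, q_value, significant, one row per shared label, in
#'   `a`'s row order), `paths`, `nulls`, `unpaired_a`/`unpaired_b` (labels
#'   present in only one matrix), and `params`.
#' @examples
#' set.seed(7)
#' a <- matrix(rnorm(3 * 9), 3, dimnames = list(c("g1", "g2", "g3"), NULL))
#' b <- matrix(rnorm(2 * 12), 2, dimnames = list(c("g3", "g1"), NULL))
#' m <- screen_matched(a, b, n_perm = 49, seed = 2)
#' m$records$entity  # g1, g3
#' @export
screen_matched <- function(a, b, timepoints_a = NULL, timepoints_b = NULL,
                           out_dir = NULL,
                           scaling = c("unit_variance", "mean_center", "none"),
                           q_threshold = 0.05, n_perm = 1000L, seed = 1L,
                           step_pattern = STEP_PATTERNS,
                           local_distance = LOCAL_DISTANCES,
                           image_format = c("jpeg", "png")) {
  scaling <- match.arg(scaling)
  step_pattern <- match.arg(step_pattern, STEP_PATTERNS)
  local_distance <- match.arg(local_distance, LOCAL_DISTANCES)
  image_format <- match.arg(image_format)
  a <- as.matrix(a); b <- as.matrix(b)
  if (is.null(rownames(a)) || is.null(rownames(b)))
    stop("both matrices need row labels for pairing")
  if (anyDuplicated(rownames(a)) || anyDuplicated(rownames(b)))
    stop("duplicate row labels make pairing ambiguous")
  if (is.null(timepoints_a)) timepoints_a <- seq_len(ncol(a))
  if (is.null(timepoints_b)) timepoints_b <- seq_len(ncol(b))
  if (anyNA(a) || anyNA(b))
    stop("missing values present; run filter_time_courses() first")

  shared <- rownames(a)[rownames(a) %in% rownames(b)]
  if (!length(shared))
    stop("no comparable entities: the row-label intersection is empty")

  params <- list(function_name = "screen_matched", scaling = scaling,
                 q_threshold = q_threshold, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), step_pattern = step_pattern,
                 local_distance = local_distance,
                 n_entities = length(shared), n_endpoints = 1L)

  pns <- vector("list", length(shared))
  sa_list <- sb_list <- vector("list", length(shared))
  for (k in seq_along(shared)) {
    lab <- shared[k]
    sa <- scale_series(time_series(a[lab, ], timepoints_a, lab), scaling)
    sb <- scale_series(time_series(b[lab, ], timepoints_b, lab), scaling)
    pns[[k]] <- permutation_pvalue(sa, sb, n_perm,
                                   seed = mix_seed(seed, lab),
                                   step_pattern = step_pattern,
                                   local_distance = local_distance,
                                   swap_invariant = TRUE)
    sa_list[[k]] <- sa; sb_list[[k]] <- sb
  }
  p <- vapply(pns, `[[`, numeric(1), "p_value")
  q <- bh_adjust(p)
  records <- data.frame(entity = shared,
                        distance = vapply(pns, `[[`, numeric(1),
                                          "observed_distance"),
                        p_value = p, q_value = q,
                        significant = q <= q_threshold,
                        row.names = NULL, stringsAsFactors = FALSE)
  names(sa_list) <- names(sb_list) <- shared
  out <- structure(list(records = records,
                        paths = lapply(pns, `[[`, "path"),
                        nulls = lapply(pns, `[[`, "null_distances"),
                        series_a = sa_list, series_b = sb_list,
                        timepoints_a = timepoints_a,
                        timepoints_b = timepoints_b,
                        unpaired_a = setdiff(rownames(a), shared),
                        unpaired_b = setdiff(rownames(b), shared),
                        params = params),
                   class = "matched_screen")
  if (!is.null(out_dir))
    write_screen_outputs(out, out_dir, image_format)
  out
}

# shared summary helpers ---------------------------------------------------

screen_records <- function(x) {
  if (inherits(x, "matched_screen") || inherits(x, "screen_result"))
    return(x$records)
  stop("no records in object of class ", paste(class(x), collapse = "/"))
}

best_record <- function(records) {
  records[order(records$q_value, records$p_value, records$entity), ][1L, ]
}

#' @export
print.endpoint_screen <- function(x, ...) {
  cat("DTW endpoint screen:", x$params$n_entities, "entities x",
      x$params$n_endpoints, "endpoints\n")
  for (r in x$results)
    cat(sprintf("  %-14s %4d significant at q <= %s\n", r$endpoint,
                sum(r$records$significant),
                format(x$params$q_threshold)))
  if (length(x$dropped))
    cat("  dropped (zero variance):", length(x$dropped), "\n")
  invisible(x)
}

#' @export
summary.endpoint_screen <- function(object, ...) {
  tab <- do.call(rbind, lapply(object$results, function(r) {
    best <- best_record(r$records)
    data.frame(endpoint = r$endpoint,
               n_significant = sum(r$records$significant),
               best_entity = best$entity, best_distance = best$distance,
               best_p = best$p_value, best_q = best$q_value,
               row.names = NULL)
  }))
  structure(list(table = tab, params = object$params),
            class = "summary.endpoint_screen")
}

#' @export
print.summary.endpoint_screen <- function(x, ...) {
  p <- x$params
  cat("DTW endpoint screen (scaling:", p$scaling, "| step:", p$step_pattern,
      "| B =", p$n_perm, "| q <=", format(p$q_threshold), ")\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' @export
print.matched_screen <- function(x, ...) {
  cat("matched DTW screen:", nrow(x$records), "shared entities;",
      sum(x$records$significant), "significant at q <=",
      format(x$params$q_threshold), "\n")
  if (length(x$unpaired_a) || length(x$unpaired_b))
    cat("  unpaired: ", length(x$unpaired_a), " only in A, ",
        length(x$unpaired_b), " only in B\n", sep = "")
  invisible(x)
}

#' @export
summary.matched_screen <- function(object, ...) {
  best <- best_record(object$records)
  cat("matched DTW screen of", nrow(object$records), "shared entities\n")
  cat("  significant at q <=", format(object$params$q_threshold), ":",
      sum(object$records$significant), "\n")
  cat("  most significant:", best$entity, "( distance",
      format(best$distance), ", p", format(best$p_value), ", q",
      format(best$q_value), ")\n")
  invisible(object)
}
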