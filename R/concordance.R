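#' Pearson correlation with a two-sided p-value
#'
#' Sample Pearson r with the usual t-transform p-value (via
#' [stats::cor.test()]), used for the per-timepoint and maximum-change
#' concordance between the two sepsis models' log2 change vectors.
#'
#' @param x,y numeric vectors of equal length >= 3, non-constant.
#' @return list with `r`, `p`, `n`.
#' @export
pearson_r <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Per-probe maximum change over time (sign retained)
#'
#' For one model, reduces its per-timepoint change profiles to a single
#' vector: each probe contributes the signed log2 change whose absolute
#' value is largest across timepoints, ties going to the earliest timepoint.
#'
#' @param profiles list of `change_profile`s for one model, in timepoint
#'   order, all over the same probe universe.
#' @return named numeric vector of signed log2 changes.
#' @export
max_change_vector <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  ids <- profiles[[1]]$probe_ids
  for (p in profiles) {
    if (!identical(p$probe_ids, ids)) stop("probe universes differ across timepoints")
  }
  d_mat <- vapply(profiles, `[[`, numeric(length(ids)), "log2_change")
  d_mat <- matrix(d_mat, nrow = length(ids))
  pick <- max.col(abs(d_mat), ties.method = "first")
  stats::setNames(d_mat[cbind(seq_along(ids), pick)], ids)
}

#' Genome-wide concordance between the two sepsis models
#'
#' Builds, on a selected probe universe, each model's mean log2 change
#' versus control per timepoint, then reports the per-timepoint Pearson
#' correlation between the models and the correlation of their
#' maximum-change vectors over time. Correlations are computed on log2
#' changes (not signed folds).
#'
#' @param expr log2 expression matrix.
#' @param samples sample annotation.
#' @param selection a `selection_result` or character vector of probe ids
#'   defining the universe (typically the union of the two models'
#'   significant probes).
#' @param timepoints timepoint labels in order; defaults to those present.
#' @return list with `per_timepoint` (data.frame: timepoint, r, p, n),
#'   `max_change` (r, r2, p, n) and the universe used.
#' @export
concordance_report <- function(expr, samples, selection, timepoints = NULL) {
  universe <- names_or_self(selection)
  if (length(universe) == 0) stop("empty selection")
  if (is.null(timepoints)) {
    timepoints <- unique(samples$timepoint[!is.na(samples$timepoint)])
  }
  prof_a <- lapply(timepoints, function(tp)
    change_profile(expr, samples, "modelA", tp, universe))
  prof_b <- lapply(timepoints, function(tp)
    change_profile(expr, samples, "modelB", tp, universe))
  per_tp <- do.call(rbind, lapply(seq_along(timepoints), function(j) {
    ct <- pearson_r(prof_a[[j]]$log2_change, prof_b[[j]]$log2_change)
    data.frame(timepoint = timepoints[j], r = ct$r, p = ct$p, n = ct$n,
               stringsAsFactors = FALSE)
  }))
  mx_a <- max_change_vector(prof_a)
  mx_b <- max_change_vector(prof_b)
  mx <- pearson_r(mx_a, mx_b)
  list(per_timepoint = per_tp,
       max_change = list(r = mx$r, r2 = mx$r^2, p = mx$p, n = mx$n),
       universe = universe)
}

#' Probe universe for cross-model concordance
#'
#' Runs the per-model F-test selection (each model's samples plus controls,
#' grouped by model:timepoint cell) and combines the two significant sets.
#' The union keeps model-unique responders (the default); the intersection
#' is available for sensitivity analysis.
#'
#' @param expr,samples as elsewhere.
#' @param alpha F-test threshold.
#' @param rule `"union"` or `"intersection"`.
#' @param probes optional probe annotation.
#' @return list with the combined `universe`, the rule, and the two
#'   per-model `selection_result`s.
#' @export
concordance_universe <- function(expr, samples, alpha = 0.001,
                                 rule = c("union", "intersection"),
                                 probes = NULL) {
  rule <- match.arg(rule)
  sel <- lapply(c("modelA", "modelB"), function(m) {
    ids <- samples$sample_id[samples$class_label %in% c("control", m)]
    f_test_selection(expr, samples, grouping = "model_time", alpha = alpha,
                     probes = probes, subset_samples = ids)
  })
  names(sel) <- c("modelA", "modelB")
  universe <- if (rule == "union") {
    union(sel$modelA$kept, sel$modelB$kept)
  } else {
    intersect(sel$modelA$kept, sel$modelB$kept)
  }
  list(universe = universe, rule = rule, selections = sel)
}
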