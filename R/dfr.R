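#' Healthy-control reference for the distance-from-reference score
#'
#' Per-probe control mean M_i and unbiased sample variance V_i (denominator
#' n - 1), computed only from samples labeled control. Probes with zero
#' control variance cannot be standardized and are excluded from the scoring
#' universe (their ids are recorded).
#'
#' @param expr log2 expression matrix.
#' @param samples sample annotation; needs >= 3 controls.
#' @param probe_subset probe ids forming the scoring universe (typically a
#'   model's significant set); defaults to all probes.
#' @return object of class `control_reference`: `M`, `V` (named vectors over
#'   the retained universe), `n_control`, `excluded_zero_var`.
#' @export
build_reference <- function(expr, samples, probe_subset = NULL) {
  ctrl <- samples$sample_id[samples$class_label == "control"]
  if (length(ctrl) < 3) stop("need at least 3 control samples")
  if (is.null(probe_subset)) probe_subset <- rownames(expr)
  if (length(probe_subset) == 0) stop("empty probe subset")
  x <- expr[probe_subset, ctrl, drop = FALSE]
  M <- rowMeans(x)
  V <- row_sds(x)^2
  zero <- V == 0
  if (any(zero)) {
    message(sum(zero), " zero-variance probe(s) excluded from DFR reference")
  }
  structure(list(M = M[!zero], V = V[!zero], n_control = length(ctrl),
                 universe = probe_subset[!zero],
                 excluded_zero_var = probe_subset[zero]),
            class = "control_reference")
}

#' Distance-from-reference (DFR) score of one sample
#'
#' The raw distance is the variance-normalized squared deviation of the
#' sample's expression from the control reference summed over the scoring
#' universe, D = sum_i (e_i - M_i)^2 / V_i, reduced to a single natural-log
#' metric dfr = ln(D). An absolute-deviation variant
#' sum_i |e_i - M_i| / sqrt(V_i) is available for sensitivity analysis.
#'
#' @param e named numeric vector of log2 expression; must cover the
#'   reference universe.
#' @param reference a `control_reference`.
#' @param variant `"squared"` (default) or `"abs"`.
#' @return list with `D`, `dfr` (= ln D; NA when degenerate), `n_probes`,
#'   `degenerate` (TRUE when D == 0).
#' @export
dfr_score <- function(e, reference, variant = c("squared", "abs")) {
  variant <- match.arg(variant)
  missing <- setdiff(reference$universe, names(e))
  if (length(missing)) {
    stop("sample missing probe(s) from reference universe: ",
         paste(utils::head(missing, 5), collapse = ", "))
  }
  ei <- e[reference$universe]
  D <- if (variant == "squared") {
    sum((ei - reference$M)^2 / reference$V)
  } else {
    sum(abs(ei - reference$M) / sqrt(reference$V))
  }
  degenerate <- D == 0
  list(D = D, dfr = if (degenerate) NA_real_ else log(D),
       n_probes = length(reference$universe), degenerate = degenerate)
}

#' DFR scores for every sample in a matrix
#'
#' @inheritParams dfr_score
#' @param expr log2 expression matrix covering the reference universe.
#' @return data.frame: `sample_id`, `D`, `dfr`, `n_probes`.
#' @export
dfr_scores <- function(expr, reference, variant = "squared") {
  rows <- lapply(colnames(expr), function(s) {
    sc <- dfr_score(expr[, s], reference, variant)
    data.frame(sample_id = s, D = sc$D, dfr = sc$dfr,
               n_probes = sc$n_probes, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Group-level DFR summary (mean with standard error)
#'
#' Aggregates per-sample DFR scores to group mean and SEM per
#' (class, timepoint) cell, including the control group itself as the
#' baseline row. SEM is reported as NA for groups of one.
#'
#' @inheritParams dfr_scores
#' @param samples sample annotation.
#' @return data.frame: `class_label`, `timepoint`, `n`, `mean_dfr`,
#'   `sem_dfr`, `mean_D`.
#' @export
group_dfr <- function(expr, samples, reference, variant = "squared") {
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  sc <- dfr_scores(expr, reference, variant)
  sc$class_label <- samples$class_label
  sc$timepoint <- ifelse(is.na(samples$timepoint), "", samples$timepoint)
  split_key <- paste(sc$class_label, sc$timepoint, sep = "|")
  rows <- lapply(split(sc, split_key), function(g) {
    data.frame(class_label = g$class_label[1], timepoint = g$timepoint[1],
               n = nrow(g),
               mean_dfr = mean(g$dfr),
               sem_dfr = if (nrow(g) > 1) stats::sd(g$dfr) / sqrt(nrow(g)) else NA_real_,
               mean_D = mean(g$D), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$class_label, out$timepoint), , drop = FALSE]
}
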