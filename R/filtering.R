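row_sds <- function(x) {
  n <- ncol(x)
  m <- rowMeans(x)
  sqrt(rowSums((x - m)^2) / (n - 1))
}

selection_result <- function(kept, statistic, threshold, probes = NULL,
                             kind = c("cv", "f_test")) {
  kind <- match.arg(kind)
  n_genes <- NA_integer_
  if (!is.null(probes)) {
    sym <- probes$gene_symbol[match(kept, probes$probe_id)]
    n_genes <- length(unique(sym[!is.na(sym)]))
  }
  structure(list(kept = kept, statistic = statistic, threshold = threshold,
                 kind = kind, n_probes = length(kept), n_genes = n_genes),
            class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat(sprintf("<selection_result> %s: %d probe set(s) kept (threshold %g)",
              x$kind, x$n_probes, x$threshold))
  if (!is.na(x$n_genes)) cat(sprintf(", %d gene(s)", x$n_genes))
  cat("\n")
  invisible(x)
}

#' Unsupervised coefficient-of-variation filter
#'
#' Keeps probe sets whose coefficient of variation (sd/mean) exceeds the
#' threshold. By default the CV is computed on the linear intensity scale
#' (values anti-logged as `2^x`), the scale on which a CV > 0.5 cut retains a
#' substantial varying fraction of a normalized array; a `log2` option
#' computes it directly on the stored values for sensitivity analysis.
#'
#' @param expr log2 expression matrix, probes x samples (>=2 samples).
#' @param threshold keep probes with CV strictly greater than this.
#' @param scale `"linear"` (default) or `"log2"`.
#' @param probes optional probe annotation for a gene count in the result.
#' @return a `selection_result`: kept probe ids, per-probe CV, counts.
#' @export
cv_filter <- function(expr, threshold = 0.5, scale = c("linear", "log2"),
                      probes = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(expr), ncol(expr) >= 2)
  x <- if (scale == "linear") 2^expr else expr
  m <- rowMeans(x)
  s <- row_sds(x)
  cv <- s / m
  bad <- m == 0
  if (any(bad)) {
    warning(sum(bad), " probe(s) with zero mean excluded from CV filter: ",
            paste(utils::head(rownames(expr)[bad], 5), collapse = ", "))
    cv[bad] <- NA_real_
  }
  kept <- rownames(expr)[!is.na(cv) & cv > threshold]
  selection_result(kept, stats::setNames(cv, rownames(expr)), threshold,
                   probes, kind = "cv")
}

grouping_factor <- function(samples, grouping = c("three_class", "model_time")) {
  grouping <- match.arg(grouping)
  if (grouping == "three_class") {
    factor(samples$class_label)
  } else {
    lab <- ifelse(samples$class_label == "control", "control",
                  paste(samples$class_label, samples$timepoint, sep = ":"))
    factor(lab)
  }
}

#' Vectorized one-way F test across all probes
#'
#' @param expr probes x samples matrix.
#' @param g factor of length `ncol(expr)` with >=2 levels, each with >=2
#'   samples.
#' @return list with per-probe `F`, `p`, and the degrees of freedom.
#' @keywords internal
row_oneway_f <- function(expr, g) {
  g <- droplevels(g)
  k <- nlevels(g)
  n <- ncol(expr)
  counts <- tabulate(g)
  if (k < 2) stop("need at least 2 groups")
  if (any(counts < 2)) {
    stop("every group needs >=2 samples; offending group(s): ",
         paste(levels(g)[counts < 2], collapse = ", "))
  }
  G <- stats::model.matrix(~ 0 + g)
  means <- (expr %*% G) / rep(counts, each = nrow(expr))
  grand <- rowSums(expr) / n
  ssb <- rowSums((means - grand)^2 %*% diag(counts, k))
  sst <- rowSums((expr - grand)^2)
  ssw <- pmax(sst - ssb, 0)
  df1 <- k - 1
  df2 <- n - k
  Fstat <- (ssb / df1) / (ssw / df2)
  p <- stats::pf(Fstat, df1, df2, lower.tail = FALSE)
  zero_w <- ssw <= .Machine$double.eps * sst
  p[zero_w & ssb > 0] <- 0
  list(F = Fstat, p = p, df1 = df1, df2 = df2, zero_within = zero_w & ssb > 0)
}

#' Supervised F-test gene selection
#'
#' Per-probe one-way ANOVA F test across the chosen grouping; probes with
#' p < alpha are kept. No multiple-testing correction is applied (the raw
#' p < 0.001 cut is the selection rule); a Benjamini-Hochberg FDR column is
#' emitted alongside for reference.
#'
#' @param expr log2 expression matrix, probes x samples.
#' @param samples sample annotation data.frame aligned to `colnames(expr)`.
#' @param grouping `"three_class"` (control / modelA / modelB, timepoints
#'   pooled) or `"model_time"` (control plus each model:timepoint cell).
#' @param alpha selection threshold on the raw p-value.
#' @param probes optional probe annotation for the gene count.
#' @param subset_samples optional character vector of sample ids to restrict
#'   to (e.g. one model plus controls).
#' @return a `selection_result`; `statistic` is a data.frame with `F`, `p`,
#'   `fdr` per probe.
#' @export
f_test_selection <- function(expr, samples,
                             grouping = c("three_class", "model_time"),
                             alpha = 0.001, probes = NULL,
                             subset_samples = NULL) {
  grouping <- match.arg(grouping)
  if (!is.null(subset_samples)) {
    samples <- samples[samples$sample_id %in% subset_samples, , drop = FALSE]
  }
  samples <- samples[match(intersect(colnames(expr), samples$sample_id),
                           samples$sample_id), , drop = FALSE]
  expr <- expr[, samples$sample_id, drop = FALSE]
  g <- grouping_factor(samples, grouping)
  res <- row_oneway_f(expr, g)
  if (any(res$zero_within)) {
    warning(sum(res$zero_within),
            " probe(s) with zero within-group variance; p set to 0")
  }
  stat <- data.frame(F = res$F, p = res$p,
                     fdr = stats::p.adjust(res$p, method = "BH"),
                     row.names = rownames(expr))
  kept <- rownames(expr)[stat$p < alpha]
  out <- selection_result(kept, stat, alpha, probes, kind = "f_test")
  out$grouping <- grouping
  out
}

#' Mean log2 change and signed fold change of a septic group versus control
#'
#' The change is the group mean minus the control mean per probe, on the log2
#' scale. Fold changes follow the reciprocal sign convention used by
#' microarray suites: a log2 change d maps to 2^d when d >= 0 and to
#' -2^(-d) when d < 0, so a halving is reported as -2 rather than 0.5.
#'
#' @param expr log2 expression matrix.
#' @param samples sample annotation.
#' @param model `"modelA"` or `"modelB"`.
#' @param timepoint timepoint label, or NULL to pool the model's samples.
#' @param probe_subset optional probe ids to restrict to.
#' @return a `change_profile`: list with `model`, `timepoint`, `probe_ids`,
#'   `log2_change`, `signed_fold` (named numeric vectors).
#' @export
change_profile <- function(expr, samples, model, timepoint = NULL,
                           probe_subset = NULL) {
  if (!is.null(probe_subset)) {
    if (length(probe_subset) == 0) stop("empty probe subset")
    expr <- expr[probe_subset, , drop = FALSE]
  }
  ctrl <- samples$sample_id[samples$class_label == "control"]
  grp <- samples$sample_id[samples$class_label == model &
                           (is.null(timepoint) | samples$timepoint %in% timepoint)]
  if (length(ctrl) == 0) stop("no control samples")
  if (length(grp) == 0) stop("no samples for ", model,
                             if (!is.null(timepoint)) paste0(" at ", timepoint))
  d <- rowMeans(expr[, grp, drop = FALSE]) - rowMeans(expr[, ctrl, drop = FALSE])
  structure(list(model = model, timepoint = timepoint,
                 probe_ids = rownames(expr),
                 log2_change = d, signed_fold = signed_fold(d)),
            class = "change_profile")
}

#' Signed (reciprocal-convention) fold change from a log2 change
#' @param d numeric log2 change(s).
#' @return signed folds: `2^d` for `d >= 0`, `-2^(-d)` otherwise.
#' @export
signed_fold <- function(d) {
  ifelse(d >= 0, 2^d, -(2^(-d)))
}

#' Log2 change from a signed fold change (inverse of [signed_fold()])
#' @param f signed fold(s), `|f| >= 1`.
#' @export
fold_to_log2 <- function(f) {
  stopifnot(all(abs(f) >= 1))
  sign(f) * log2(abs(f))
}

#' Collapse two probe-level selections to genes and count the overlap
#'
#' A gene counts as significant for a model when at least one of its probe
#' sets is selected. Probes without a gene symbol are excluded from the
#' gene-level sets (but counted at the probe level).
#'
#' @param sel_a,sel_b `selection_result`s over the same probe universe.
#' @param probes probe annotation data.frame.
#' @return list with probe-level and gene-level sets and counts:
#'   `genes_a`, `genes_b`, `genes_common`, `genes_only_a`, `genes_only_b`,
#'   the probe-level counterparts, and a `counts` summary vector.
#' @export
collapse_and_overlap <- function(sel_a, sel_b, probes) {
  universe_a <- names_or_self(sel_a)
  universe_b <- names_or_self(sel_b)
  to_genes <- function(ids) {
    sym <- probes$gene_symbol[match(ids, probes$probe_id)]
    unique(sym[!is.na(sym)])
  }
  ga <- to_genes(universe_a)
  gb <- to_genes(universe_b)
  pc <- intersect(universe_a, universe_b)
  gc_ <- intersect(ga, gb)
  out <- list(
    probes_a = universe_a, probes_b = universe_b, probes_common = pc,
    probes_only_a = setdiff(universe_a, pc), probes_only_b = setdiff(universe_b, pc),
    genes_a = ga, genes_b = gb, genes_common = gc_,
    genes_only_a = setdiff(ga, gc_), genes_only_b = setdiff(gb, gc_))
  out$counts <- vapply(out, length, 0L)
  out
}

names_or_self <- function(x) {
  if (inherits(x, "selection_result")) x$kept else as.character(x)
}

#' Hierarchical ordering of probes and samples for heat-map export
#'
#' Average-linkage agglomerative clustering on 1 - Pearson correlation
#' distance, applied to rows (probes) and columns (samples). Constant rows
#' (zero variance, correlation undefined) are placed last with a warning.
#' The ordering is deterministic for a fixed input.
#'
#' @param expr log2 expression matrix.
#' @param probe_subset optional probe ids to restrict to (>=2).
#' @return list with `probe_order` and `sample_order` (ids in dendrogram
#'   order) and the two `hclust` objects.
#' @export
cluster_order <- function(expr, probe_subset = NULL) {
  if (!is.null(probe_subset)) expr <- expr[probe_subset, , drop = FALSE]
  stopifnot(nrow(expr) >= 2, ncol(expr) >= 2)
  row_const <- row_sds(expr) == 0
  if (any(row_const)) {
    warning(sum(row_const), " constant probe(s) placed last in the ordering")
  }
  work <- expr[!row_const, , drop = FALSE]
  hr <- if (nrow(work) >= 2) {
    stats::hclust(stats::as.dist(1 - stats::cor(t(work))), method = "average")
  } else NULL
  hc <- stats::hclust(stats::as.dist(1 - stats::cor(work)), method = "average")
  probe_order <- c(if (is.null(hr)) rownames(work) else rownames(work)[hr$order],
                   rownames(expr)[row_const])
  list(probe_order = probe_order,
       sample_order = colnames(expr)[hc$order],
       probe_hclust = hr, sample_hclust = hc)
}
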