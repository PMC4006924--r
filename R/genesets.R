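#' Fisher over-representation of a gene set among significant genes
#'
#' 2x2 exact test (in-set vs out-of-set crossed with significant vs not)
#' over a gene universe, reported as the two-sided Fisher p and its
#' -log10 transform (so the conventional p = 0.05 line sits at 1.3).
#'
#' @param gene_set a gene set (list with `name`, `genes`, optional
#'   `directions`), as from [read_gene_sets()].
#' @param significant_genes character vector, subset of `universe`.
#' @param universe character vector of all genes considered (typically every
#'   annotated gene on the array).
#' @return list: `name`, contingency `counts` (named length-4), `p`,
#'   `minus_log10_p`, `n_set_in_universe`.
#' @export
fisher_enrichment <- function(gene_set, significant_genes, universe) {
  if (length(universe) == 0) stop("empty gene universe")
  universe <- unique(universe)
  significant_genes <- unique(significant_genes)
  if (!all(significant_genes %in% universe)) {
    stop("significant genes must be a subset of the universe")
  }
  set_genes <- intersect(gene_set$genes, universe)
  if (length(set_genes) == 0) {
    stop("set ", gene_set$name, " has no genes in the universe")
  }
  a <- length(intersect(set_genes, significant_genes))        # in set & sig
  b <- length(set_genes) - a                                  # in set & not
  c_ <- length(significant_genes) - a                         # out & sig
  d <- length(universe) - a - b - c_                          # out & not
  tab <- matrix(c(a, b, c_, d), nrow = 2)
  p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
  p <- min(p, 1)
  list(name = gene_set$name,
       counts = c(set_sig = a, set_notsig = b, out_sig = c_, out_notsig = d),
       p = p, minus_log10_p = -log10(p),
       n_set_in_universe = length(set_genes))
}

#' Collapse a probe-level change profile to gene-level signed folds
#'
#' Each gene is represented by the probe with the largest absolute signed
#' fold among its probe sets (ties to the first probe in matrix order);
#' probes without a gene symbol are skipped.
#'
#' @param profile a `change_profile`.
#' @param probes probe annotation data.frame.
#' @return named numeric vector of signed folds, one per gene.
#' @export
gene_changes <- function(profile, probes) {
  sym <- probes$gene_symbol[match(profile$probe_ids, probes$probe_id)]
  keep <- !is.na(sym)
  f <- profile$signed_fold[keep]
  sym <- sym[keep]
  picked <- tapply(seq_along(f), sym, function(idx) idx[which.max(abs(f[idx]))])
  stats::setNames(f[unlist(picked)], names(picked))
}

#' Directional activation Z-score of a gene set
#'
#' Over the set's genes whose observed |signed fold| passes the inclusion
#' threshold, Z = (N_consistent - N_inconsistent) / sqrt(N), where a gene is
#' consistent when the sign of its observed change equals its expected
#' regulation direction. |Z| >= 2 is flagged significant (the two-sided 95%
#' normal band). Z = 0 when no gene passes.
#'
#' @param gene_set gene set with a `directions` component (+1 / -1 per gene).
#' @param gene_folds named numeric vector of observed signed folds per gene
#'   (see [gene_changes()]).
#' @param fold_threshold inclusion rule |fold| >= fold_threshold (>= 1);
#'   default 2, the conventional two-fold-change cut.
#' @return list: `z`, `n` (genes passing), `n_consistent`, `n_inconsistent`,
#'   `significant` (|Z| >= 2).
#' @export
activation_z <- function(gene_set, gene_folds, fold_threshold = 2) {
  if (is.null(gene_set$directions)) {
    stop("set ", gene_set$name, " has no expected directions")
  }
  stopifnot(fold_threshold >= 1)
  genes <- intersect(gene_set$genes, names(gene_folds))
  f <- gene_folds[genes]
  f <- f[abs(f) >= fold_threshold]
  n <- length(f)
  if (n == 0) {
    return(list(z = 0, n = 0L, n_consistent = 0L, n_inconsistent = 0L,
                significant = FALSE))
  }
  expected <- gene_set$directions[names(f)]
  consistent <- sign(f) == sign(expected)
  z <- (sum(consistent) - sum(!consistent)) / sqrt(n)
  list(z = z, n = n, n_consistent = sum(consistent),
       n_inconsistent = sum(!consistent), significant = abs(z) >= 2)
}

#' Enrichment and activation table over a collection of gene sets
#'
#' Convenience wrapper combining [fisher_enrichment()] and, where a set
#' carries directions, [activation_z()] for one model/timepoint change
#' profile.
#'
#' @param sets list of gene sets.
#' @param significant_genes,universe as in [fisher_enrichment()].
#' @param gene_folds named signed folds per gene (for the Z column); NULL
#'   skips activation scoring.
#' @param fold_threshold inclusion rule for the Z-score.
#' @return data.frame with one row per set: counts, `p`, `minus_log10_p`,
#'   `z`, `z_n`, `significant_z`.
#' @export
geneset_table <- function(sets, significant_genes, universe,
                          gene_folds = NULL, fold_threshold = 2) {
  rows <- lapply(sets, function(s) {
    fe <- fisher_enrichment(s, significant_genes, universe)
    z <- z_n <- NA_real_
    sig_z <- NA
    if (!is.null(gene_folds) && !is.null(s$directions)) {
      az <- activation_z(s, gene_folds, fold_threshold)
      z <- az$z; z_n <- az$n; sig_z <- az$significant
    }
    data.frame(set = fe$name,
               set_sig = fe$counts[["set_sig"]],
               set_size = fe$n_set_in_universe,
               p = fe$p, minus_log10_p = fe$minus_log10_p,
               z = z, z_n = z_n, significant_z = sig_z,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
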