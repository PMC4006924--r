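#' Leave-one-out cross-validated misclassification rate
#'
#' Each sample is held out in turn; the F-test gene selection is (by default)
#' re-run on the remaining samples at `selector_alpha`, a nearest-centroid
#' classifier is trained on the selected probes (standardized Euclidean
#' distance, per-probe pooled within-class sd), and the held-out label is
#' predicted. If no probe passes the per-fold selection, the single
#' smallest-p probe is used so the classifier is always defined.
#'
#' The fold loop works on precomputed per-probe group sums and sums of
#' squares, subtracting the held-out column, so the full permutation null
#' (which repeats the LOOCV hundreds of times) stays tractable on
#' genome-scale matrices.
#'
#' @param expr log2 expression matrix, probes x samples.
#' @param samples sample annotation; classification target is `class_label`.
#' @param selector_alpha p-value cut for per-fold selection.
#' @param reselect_per_fold logical; FALSE reuses one selection computed on
#'   all samples (the optimistic variant with selection bias).
#' @param grouping grouping passed to the selector.
#' @return list with `rate`, a `calls` data.frame (sample, true, predicted),
#'   and `n_selected` per fold.
#' @export
loocv_rate <- function(expr, samples, selector_alpha = 0.001,
                       reselect_per_fold = TRUE,
                       grouping = "three_class") {
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  y <- factor(samples$class_label)
  if (any(tabulate(y) < 2)) stop("every class needs >=2 samples")
  n <- ncol(expr)
  np <- nrow(expr)

  g_sel <- grouping_factor(samples, grouping)
  gi <- as.integer(g_sel); k_sel <- nlevels(g_sel)
  yi <- as.integer(y); k_y <- nlevels(y)

  tot <- rowSums(expr)
  totsq <- rowSums(expr^2)
  group_sums <- function(idx, k) {
    out <- matrix(0, np, k)
    for (j in seq_len(k)) out[, j] <- rowSums(expr[, idx == j, drop = FALSE])
    out
  }
  S_sel <- group_sums(gi, k_sel)
  S_y <- if (identical(gi, yi)) S_sel else group_sums(yi, k_y)
  cnt_sel <- tabulate(gi, k_sel)
  cnt_y <- tabulate(yi, k_y)

  global_sel <- if (!reselect_per_fold) {
    res <- row_oneway_f(expr, g_sel)
    kept <- which(res$p < selector_alpha)
    if (length(kept) == 0) kept <- which.min(res$p)
    kept
  } else NULL

  pred <- character(n)
  n_selected <- integer(n)
  n1 <- n - 1
  for (i in seq_len(n)) {
    xi <- expr[, i]
    cy <- cnt_y; cy[yi[i]] <- cy[yi[i]] - 1L
    if (any(cy < 2)) {
      stop("holdout reduces class '", samples$class_label[i], "' below 2 samples")
    }
    T1 <- tot - xi
    Q1 <- totsq - xi^2
    correction <- T1^2 / n1

    if (reselect_per_fold) {
      cs <- cnt_sel; cs[gi[i]] <- cs[gi[i]] - 1L
      if (any(cs < 2)) {
        stop("holdout leaves selector group '",
             levels(g_sel)[which(cs < 2)[1]], "' with <2 samples")
      }
      ssb <- -correction
      for (j in seq_len(k_sel)) {
        Sj <- S_sel[, j]; if (j == gi[i]) Sj <- Sj - xi
        ssb <- ssb + Sj^2 / cs[j]
      }
      ssw <- pmax(Q1 - correction - ssb, 0)
      df1 <- k_sel - 1; df2 <- n1 - k_sel
      pv <- stats::pf((ssb / df1) / (ssw / df2), df1, df2, lower.tail = FALSE)
      pv[ssw == 0 & ssb > 0] <- 0
      sel <- which(pv < selector_alpha)
      if (length(sel) == 0) sel <- which.min(pv)
    } else {
      sel <- global_sel
    }
    n_selected[i] <- length(sel)

    # nearest centroid on the selected probes, standardized by the pooled
    # within-class sd of the training fold
    ssb_y <- -correction[sel]
    cent <- matrix(0, length(sel), k_y)
    for (j in seq_len(k_y)) {
      Sj <- S_y[sel, j]; if (j == yi[i]) Sj <- Sj - xi[sel]
      cent[, j] <- Sj / cy[j]
      ssb_y <- ssb_y + Sj^2 / cy[j]
    }
    ssw_y <- pmax(Q1[sel] - correction[sel] - ssb_y, 0)
    s <- sqrt(ssw_y / (n1 - k_y))
    if (any(s == 0)) {
      s[s == 0] <- if (any(s > 0)) min(s[s > 0], 1) else 1
    }
    z <- (xi[sel] - cent) / s
    pred[i] <- levels(y)[which.min(colSums(z^2))]  # ties -> first class level
  }
  calls <- data.frame(sample_id = samples$sample_id,
                      true = as.character(y), predicted = pred,
                      stringsAsFactors = FALSE)
  list(rate = mean(pred != as.character(y)), calls = calls,
       n_selected = n_selected)
}

#' Permutation p-value for the LOOCV misclassification rate
#'
#' Class labels are permuted jointly across the whole cohort (controls
#' included) `n_permutations` times; the full LOOCV procedure, including any
#' per-fold reselection, is repeated for each permutation. The add-one
#' Monte-Carlo p-value is (1 + #\{null rate <= observed\}) / (B + 1), so it is
#' never zero.
#'
#' @inheritParams loocv_rate
#' @param n_permutations number of label permutations B (>= 1).
#' @param seed integer seed controlling the permutations.
#' @return list with `observed_rate`, `calls`, `null_rates`,
#'   `n_permutations`, and `p_value`.
#' @export
permutation_pvalue <- function(expr, samples, selector_alpha = 0.001,
                               reselect_per_fold = TRUE,
                               grouping = "three_class",
                               n_permutations = 1000, seed = 1L) {
  stopifnot(n_permutations >= 1)
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  obs <- loocv_rate(expr, samples, selector_alpha, reselect_per_fold, grouping)
  set.seed(seed)
  null_rates <- vapply(seq_len(n_permutations), function(b) {
    perm <- samples
    perm$class_label <- sample(perm$class_label)
    loocv_rate(expr, perm, selector_alpha, reselect_per_fold, grouping)$rate
  }, 0)
  p <- (1 + sum(null_rates <= obs$rate)) / (n_permutations + 1)
  list(observed_rate = obs$rate, calls = obs$calls,
       null_rates = null_rates, n_permutations = n_permutations,
       p_value = p)
}
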