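# Shared fixture builders. Everything is generated in code; no stored data.

# i.i.d. null matrix with a three-class cohort (control / modelA / modelB)
null_cohort <- function(n_probes = 50, n_per_class = 4, timepoint = "2h",
                        seed = 1) {
  set.seed(seed)
  n <- 3 * n_per_class
  expr <- matrix(rnorm(n_probes * n),
                 n_probes, n,
                 dimnames = list(sprintf("pr%04d", seq_len(n_probes)),
                                 sprintf("s%03d", seq_len(n))))
  samples <- data.frame(
    sample_id = colnames(expr),
    class_label = rep(c("control", "modelA", "modelB"), each = n_per_class),
    timepoint = c(rep(NA_character_, n_per_class), rep(timepoint, 2 * n_per_class)),
    stringsAsFactors = FALSE)
  list(expr = expr, samples = samples)
}

# probe annotation where every probe is its own gene
identity_probes <- function(probe_ids) {
  data.frame(probe_id = probe_ids, gene_symbol = probe_ids,
             stringsAsFactors = FALSE)
}

# a clearly separable three-class design (single timepoint, big effects);
# 5 samples per class keep the chance that a random label permutation
# reproduces the true partition (which would tie the null rate at 0)
# negligible at B = 999
separable_design <- function(seed = 5, n_probes = 200) {
  synthetic_design(n_probes = n_probes, n_control = 5, n_per_group = 5,
                   timepoints = "2h", rho_per_timepoint = 0,
                   de_fraction = 0.3, effect_sd = 3, noise_sd = 0.25,
                   seed = seed)
}

# brute-force two-sided Fisher p by full hypergeometric enumeration
fisher_enum_p <- function(a, b, c_, d) {
  K <- a + b          # set size
  S <- a + c_         # significant
  N <- a + b + c_ + d
  support <- max(0, S - (N - K)):min(K, S)
  probs <- dhyper(support, K, N - K, S)
  obs <- dhyper(a, K, N - K, S)
  sum(probs[probs <= obs * (1 + 1e-7)])
}

# naive average-linkage agglomeration on a distance matrix; returns merge
# heights in order, independent of stats::hclust
average_linkage_heights <- function(D) {
  n <- nrow(D)
  active <- as.list(seq_len(n))
  heights <- numeric(0)
  dmat <- D
  diag(dmat) <- Inf
  while (length(active) > 1) {
    k <- length(active)
    best <- c(1, 2); best_d <- Inf
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        dij <- mean(D[active[[i]], active[[j]]])
        if (dij < best_d) { best_d <- dij; best <- c(i, j) }
      }
    }
    heights <- c(heights, best_d)
    merged <- c(active[[best[1]]], active[[best[2]]])
    active <- c(active[-best], list(merged))
  }
  heights
}

# oracle LOOCV with nearest centroid on all probes (standardized Euclidean)
oracle_loocv_calls <- function(expr, classes) {
  n <- ncol(expr)
  preds <- character(n)
  for (i in seq_len(n)) {
    tr <- expr[, -i, drop = FALSE]
    y <- classes[-i]
    lev <- sort(unique(y))
    cent <- sapply(lev, function(l) rowMeans(tr[, y == l, drop = FALSE]))
    ssw <- 0
    for (l in lev) {
      block <- tr[, y == l, drop = FALSE]
      ssw <- ssw + rowSums((block - rowMeans(block))^2)
    }
    s <- sqrt(ssw / (ncol(tr) - length(lev)))
    s[s == 0] <- min(s[s > 0], 1)
    d2 <- colSums(((expr[, i] - cent) / s)^2)
    preds[i] <- lev[which.min(d2)]
  }
  preds
}
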