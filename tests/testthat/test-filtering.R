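test_that("CV filter computes sd/mean on the requested scale", {
  # linear values (40, 100, 160): mean 100, sd 60, CV 0.6 > 0.5
  expr <- rbind(high = log2(c(40, 100, 160)),
                flat = log2(c(100, 100, 100)))
  colnames(expr) <- c("a", "b", "c")
  sel <- cv_filter(expr, threshold = 0.5, scale = "linear")
  expect_equal(unname(sel$statistic["high"]), 0.6, tolerance = 1e-12)
  expect_equal(sel$kept, "high")
  # a constant probe has CV 0 and is dropped at any positive threshold
  expect_equal(unname(sel$statistic["flat"]), 0)
  expect_equal(cv_filter(expr, threshold = 1e-9)$kept, "high")
})

test_that("CV filter agrees with a brute-force per-probe recomputation", {
  set.seed(101)
  expr <- matrix(rnorm(50 * 10, 8, 1.5), 50, 10,
                 dimnames = list(sprintf("p%02d", 1:50), sprintf("s%02d", 1:10)))
  for (scale in c("linear", "log2")) {
    sel <- cv_filter(expr, threshold = 0.4, scale = scale)
    kept_oracle <- character(0)
    for (i in seq_len(nrow(expr))) {
      v <- if (scale == "linear") 2^expr[i, ] else expr[i, ]
      if (sd(v) / mean(v) > 0.4) kept_oracle <- c(kept_oracle, rownames(expr)[i])
    }
    expect_identical(sel$kept, kept_oracle)
  }
})

test_that("F-test selection matches stats oracles and handles degenerate groups", {
  co <- null_cohort(n_probes = 40, n_per_class = 4, seed = 7)
  sel <- f_test_selection(co$expr, co$samples, "three_class", alpha = 0.05)
  g <- factor(co$samples$class_label)
  for (i in c(1, 13, 40)) {
    ref <- oneway.test(co$expr[i, ] ~ g, var.equal = TRUE)
    expect_equal(sel$statistic$p[i], ref$p.value, tolerance = 1e-10)
    expect_equal(sel$statistic$F[i], unname(ref$statistic), tolerance = 1e-10)
  }
  # two-group case: F-test p equals the squared-t equal-variance p
  two <- co$samples[co$samples$class_label != "modelB", ]
  sel2 <- f_test_selection(co$expr, two, "three_class", alpha = 0.05,
                           subset_samples = two$sample_id)
  tt <- t.test(co$expr[5, two$sample_id[two$class_label == "control"]],
               co$expr[5, two$sample_id[two$class_label == "modelA"]],
               var.equal = TRUE)
  expect_equal(sel2$statistic$p[5], tt$p.value, tolerance = 1e-10)
  expect_equal(sel2$statistic$F[5], unname(tt$statistic)^2, tolerance = 1e-10)
  # a group with < 2 samples is an error
  bad <- co$samples[-(5:7), ]
  expect_error(f_test_selection(co$expr, bad, subset_samples = bad$sample_id),
               ">=2 samples")
})

test_that("a huge injected effect is always selected; zero within-variance warns", {
  co <- null_cohort(n_probes = 20, n_per_class = 4, seed = 8)
  co$expr[3, co$samples$class_label == "modelA"] <-
    co$expr[3, co$samples$class_label == "modelA"] + 10
  sel <- f_test_selection(co$expr, co$samples)
  expect_true("pr0003" %in% sel$kept)
  expect_lt(sel$statistic["pr0003", "p"], 1e-6)

  co$expr[5, ] <- rep(c(0, 1, 2), each = 4)  # identical within each class
  expect_warning(sel <- f_test_selection(co$expr, co$samples),
                 "zero within-group variance")
  expect_equal(sel$statistic["pr0005", "p"], 0)
})

test_that("selection is invariant to sample column order", {
  co <- null_cohort(n_probes = 30, n_per_class = 4, seed = 9)
  sel1 <- f_test_selection(co$expr, co$samples, alpha = 0.1)
  perm <- sample(ncol(co$expr))
  sel2 <- f_test_selection(co$expr[, perm], co$samples, alpha = 0.1)
  expect_identical(sort(sel1$kept), sort(sel2$kept))
})

test_that("F-test p-values decrease (stochastically) with injected effect size", {
  set.seed(30)
  deltas <- c(0, 0.5, 1, 2, 4)
  mean_p <- sapply(deltas, function(delta) {
    mean(replicate(20, {
      co <- null_cohort(n_probes = 1, n_per_class = 4,
                        seed = sample.int(1e6, 1))
      co$expr[1, co$samples$class_label == "modelB"] <-
        co$expr[1, co$samples$class_label == "modelB"] + delta
      f_test_selection(co$expr, co$samples, alpha = 0.5)$statistic$p
    }))
  })
  expect_true(all(diff(mean_p) <= 0))
})

test_that("change profiles follow the signed-fold conventions", {
  expr <- rbind(p1 = c(5, 5, 7, 7),    # d = +2 -> fold +4
                p2 = c(5, 5, 4, 4),    # d = -1 -> fold -2
                p3 = c(5, 5, 5, 5))    # d =  0 -> fold +1
  colnames(expr) <- c("c1", "c2", "m1", "m2")
  samples <- data.frame(sample_id = colnames(expr),
                        class_label = c("control", "control", "modelA", "modelA"),
                        timepoint = c(NA, NA, "2h", "2h"))
  cp <- change_profile(expr, samples, "modelA", "2h")
  expect_equal(unname(cp$log2_change), c(2, -1, 0))
  expect_equal(unname(cp$signed_fold), c(4, -2, 1))
  expect_error(change_profile(expr, samples, "modelA", "2h", character(0)),
               "empty probe subset")
  expect_error(change_profile(expr, samples, "modelB", "2h"), "no samples")
})

test_that("signed fold and log2 change round-trip; |fold| >= 1 always", {
  d <- seq(-4, 4, by = 0.25)
  f <- signed_fold(d)
  expect_true(all(abs(f) >= 1))
  expect_equal(fold_to_log2(f), d)
  expect_equal(sign(f[d != 0]), sign(d[d != 0]))
})

test_that("an injected Il-6-like fold is recovered from noisy data", {
  # model B, 2h effect of log2(31.1): cytokine-scale up-regulation
  target <- 31.1
  d <- synthetic_design(n_probes = 50, n_control = 10, n_per_group = 4,
                        timepoints = "2h", de_fraction = 0, noise_sd = 0.15,
                        seed = 77)
  ds <- generate_dataset(d)
  bs <- ds$samples$class_label == "modelB"
  ds$expr[1, bs] <- ds$expr[1, bs] + log2(target)
  cp <- change_profile(ds$expr, ds$samples, "modelB", "2h")
  # standard error of d is noise_sd * sqrt(1/4 + 1/10) ~ 0.09 log2 units
  expect_equal(unname(cp$log2_change[1]), log2(target), tolerance = 0.35 / log2(target))
  expect_gt(cp$signed_fold[1], target / 1.3)
  expect_lt(cp$signed_fold[1], target * 1.3)
})

test_that("gene collapsing and overlap accounting follow set algebra", {
  probes <- identity_probes(sprintf("g%d", 1:8))
  ov <- collapse_and_overlap(sprintf("g%d", 1:5), sprintf("g%d", 4:8), probes)
  expect_equal(unname(ov$counts[c("genes_common", "genes_only_a", "genes_only_b")]),
               c(2L, 3L, 3L))
  ov2 <- collapse_and_overlap(sprintf("g%d", 1:5), sprintf("g%d", 1:5), probes)
  expect_equal(unname(ov2$counts["genes_common"]), 5L)
  expect_equal(unname(ov2$counts["genes_only_a"]), 0L)
  # several probes per gene: gene significant iff >= 1 probe selected
  probes2 <- data.frame(probe_id = c("p1", "p2", "p3", "p4"),
                        gene_symbol = c("gA", "gA", "gB", NA))
  ov3 <- collapse_and_overlap(c("p1", "p4"), c("p2", "p3"), probes2)
  expect_equal(ov3$genes_a, "gA")
  expect_setequal(ov3$genes_b, c("gA", "gB"))
  expect_equal(ov3$genes_common, "gA")
  expect_equal(unname(ov3$counts["probes_a"]), 2L)  # unannotated probe still counted
})

test_that("cluster ordering is deterministic and respects correlation distance", {
  set.seed(55)
  expr <- matrix(rnorm(20 * 8), 20, 8,
                 dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:8)))
  expr[, 2] <- expr[, 1]  # identical samples must end up adjacent
  ord <- cluster_order(expr)
  pos <- match(c("s01", "s02"), ord$sample_order)
  expect_equal(abs(diff(pos)), 1)
  expect_identical(ord$probe_order, cluster_order(expr)$probe_order)
  # perfectly anticorrelated probes sit at the maximal distance 2
  anti <- rbind(a = 1:8, b = -(1:8), c = rnorm(8))
  colnames(anti) <- sprintf("s%d", 1:8)
  D <- as.matrix(1 - cor(t(anti)))
  expect_equal(D["a", "b"], 2)
  # constant probes are placed last, with a warning
  expr[5, ] <- 3
  expect_warning(ord2 <- cluster_order(expr), "constant probe")
  expect_equal(tail(ord2$probe_order, 1), "p05")
})

test_that("average-linkage merge heights match a naive agglomerative oracle", {
  set.seed(56)
  expr <- matrix(rnorm(20 * 10), 20, 10,
                 dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:10)))
  ord <- cluster_order(expr)
  D <- as.matrix(1 - cor(t(expr)))
  expect_equal(ord$probe_hclust$height, average_linkage_heights(D),
               tolerance = 1e-10)
})
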