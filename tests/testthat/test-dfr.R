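ctrl_block <- function(n_probes = 20, n_control = 6, seed = 1, noise_sd = 1) {
  set.seed(seed)
  mu <- runif(n_probes, 4, 14)
  expr <- matrix(rnorm(n_probes * n_control, mu, noise_sd), n_probes, n_control,
                 dimnames = list(sprintf("p%03d", seq_len(n_probes)),
                                 sprintf("c%02d", seq_len(n_control))))
  samples <- data.frame(sample_id = colnames(expr), class_label = "control",
                        timepoint = NA_character_)
  list(expr = expr, samples = samples, mu = mu)
}

test_that("control reference holds per-probe mean and unbiased variance", {
  expr <- matrix(c(4, 6, 5, 5, 1, 3), 3, 2, byrow = TRUE,
                 dimnames = list(c("p1", "p2", "p3"), c("c1", "c2", "c3")[1:2]))
  samples <- data.frame(sample_id = c("c1", "c2"),
                        class_label = "control", timepoint = NA_character_)
  expect_error(build_reference(expr, samples), "at least 3 control")
  cb <- ctrl_block(n_probes = 1000, n_control = 10, seed = 41)
  ref <- build_reference(cb$expr, cb$samples)
  # independent per-row loop oracle
  for (i in c(1, 500, 1000)) {
    expect_equal(unname(ref$M[i]), mean(cb$expr[i, ]))
    expect_equal(unname(ref$V[i]), var(cb$expr[i, ]))
  }
  expect_equal(ref$n_control, 10)
  # the two-point case: controls (4, 6) -> M 5, V 2
  cb3 <- ctrl_block(n_probes = 2, n_control = 3, seed = 42)
  cb3$expr[1, ] <- c(4, 6, 5)
  ref3 <- build_reference(cb3$expr, cb3$samples)
  expect_equal(unname(ref3$M["p001"]), 5)
  expect_equal(unname(ref3$V["p001"]), 1)
})

test_that("zero-variance probes are excluded from the reference with a note", {
  cb <- ctrl_block(n_probes = 5, n_control = 4, seed = 43)
  cb$expr[2, ] <- 7
  expect_message(ref <- build_reference(cb$expr, cb$samples), "zero-variance")
  expect_false("p002" %in% ref$universe)
  expect_equal(ref$excluded_zero_var, "p002")
})

test_that("the DFR score is the variance-normalized squared deviation sum", {
  ref <- structure(list(M = c(p1 = 1, p2 = 4), V = c(p1 = 1, p2 = 1),
                        n_control = 5, universe = c("p1", "p2"),
                        excluded_zero_var = character(0)),
                   class = "control_reference")
  sc <- dfr_score(c(p1 = 3, p2 = 5), ref)
  expect_equal(sc$D, 5)                      # (3-1)^2/1 + (5-4)^2/1
  expect_equal(sc$dfr, log(5))               # single natural-log metric
  # identical to the reference mean: degenerate, no log
  sc0 <- dfr_score(c(p1 = 1, p2 = 4), ref)
  expect_equal(sc0$D, 0)
  expect_true(sc0$degenerate)
  expect_true(is.na(sc0$dfr))
  # a probe sitting exactly at its control mean contributes nothing
  ref3 <- structure(list(M = c(p1 = 1, p2 = 4, p3 = 2),
                         V = c(p1 = 1, p2 = 1, p3 = 3), n_control = 5,
                         universe = c("p1", "p2", "p3"),
                         excluded_zero_var = character(0)),
                    class = "control_reference")
  expect_equal(dfr_score(c(p1 = 3, p2 = 5, p3 = 2), ref3)$D, 5)
  expect_error(dfr_score(c(p1 = 3), ref), "missing probe")
  # absolute-deviation variant for sensitivity analysis
  expect_equal(dfr_score(c(p1 = 3, p2 = 5), ref, variant = "abs")$D, 3)
})

test_that("D is additive over disjoint probe subsets and order-invariant", {
  cb <- ctrl_block(n_probes = 40, n_control = 6, seed = 44)
  ref_all <- build_reference(cb$expr, cb$samples)
  ref_a <- build_reference(cb$expr, cb$samples, rownames(cb$expr)[1:15])
  ref_b <- build_reference(cb$expr, cb$samples, rownames(cb$expr)[16:40])
  set.seed(45)
  e <- setNames(rnorm(40, cb$mu, 1), rownames(cb$expr))
  expect_equal(dfr_score(e, ref_all)$D,
               dfr_score(e, ref_a)$D + dfr_score(e, ref_b)$D)
  expect_equal(dfr_score(e[sample(40)], ref_all)$D, dfr_score(e, ref_all)$D)
})

test_that("D is invariant to a joint rescaling of expression and reference", {
  cb <- ctrl_block(n_probes = 30, n_control = 6, seed = 46)
  set.seed(47)
  e <- setNames(rnorm(30, cb$mu, 1), rownames(cb$expr))
  ref1 <- build_reference(cb$expr, cb$samples)
  ref2 <- build_reference(3 * cb$expr, cb$samples)  # scales M by 3, V by 9
  expect_equal(dfr_score(3 * e, ref2)$D, dfr_score(e, ref1)$D)
})

test_that("injecting a larger effect strictly increases D", {
  cb <- ctrl_block(n_probes = 50, n_control = 8, seed = 48)
  ref <- build_reference(cb$expr, cb$samples)
  set.seed(49)
  e <- setNames(rnorm(50, cb$mu, 1), rownames(cb$expr))
  signs <- sample(c(-1, 1), 50, replace = TRUE)
  Ds <- sapply(c(0.5, 1, 2, 4, 8), function(delta)
    dfr_score(e + delta * signs, ref)$D)
  expect_true(all(diff(Ds) > 0))
})

test_that("null samples concentrate near the analytic scaled-F expectation", {
  # E[D/G] for a control-like draw = (1 + 1/n) (n-1)/(n-3); n = 10 -> ~1.414
  n_ctrl <- 10; G <- 400; n_draws <- 400
  cb <- ctrl_block(n_probes = G, n_control = n_ctrl, seed = 50, noise_sd = 0.8)
  ref <- build_reference(cb$expr, cb$samples)
  set.seed(51)
  draws <- matrix(rnorm(G * n_draws, cb$mu, 0.8), G, n_draws,
                  dimnames = list(rownames(cb$expr), sprintf("d%04d", 1:n_draws)))
  ratio <- mean(dfr_scores(draws, ref)$D) / length(ref$universe)
  expected <- (1 + 1 / n_ctrl) * (n_ctrl - 1) / (n_ctrl - 3)
  expect_equal(ratio, expected, tolerance = 0.1)
})

test_that("group summaries report mean, SEM and the control baseline", {
  cb <- ctrl_block(n_probes = 30, n_control = 5, seed = 52)
  ref <- build_reference(cb$expr, cb$samples)
  set.seed(53)
  septic <- matrix(rnorm(30 * 3, cb$mu + 1, 1), 30, 3,
                   dimnames = list(rownames(cb$expr), c("m1", "m2", "m3")))
  expr <- cbind(cb$expr, septic)
  samples <- rbind(cb$samples,
                   data.frame(sample_id = c("m1", "m2", "m3"),
                              class_label = "modelA",
                              timepoint = c("2h", "2h", "1d")))
  g <- group_dfr(expr, samples, ref)
  expect_setequal(g$class_label, c("control", "modelA"))
  expect_true(is.na(g$sem_dfr[g$timepoint == "1d"]))     # group of one
  expect_false(anyNA(g$sem_dfr[g$class_label == "control"]))
  per_sample <- dfr_scores(expr[, c("m1", "m2")], ref)
  expect_equal(g$mean_dfr[g$timepoint == "2h"], mean(per_sample$dfr))
})
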