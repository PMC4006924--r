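#' Design for a synthetic two-model sepsis expression dataset
#'
#' Describes a simulated cohort with the structure the downstream analyses
#' assume: a healthy-control group plus two sepsis models sampled at several
#' timepoints, a designated fraction of differentially expressed (DE) probe
#' sets, and a tunable per-timepoint correlation between the two models'
#' log2 effect vectors. The generator draws, for each DE probe and timepoint,
#' a bivariate-normal pair of log2 effects (one per model) with standard
#' deviation `effect_sd` and correlation `rho_per_timepoint[t]`; non-DE
#' probes carry an effect of exactly zero (a sharp null, so type-I-error
#' calibration of the F-test is exact).
#'
#' @param n_probes number of probe sets on the simulated array.
#' @param probes_per_gene probe sets per gene symbol. The default 1.5
#'   alternates genes with 1 and 2 probe sets (average 1.5), exercising the
#'   probe-set/gene count distinction; an integer gives constant blocks.
#' @param n_control number of healthy-control samples (no timepoint).
#' @param n_per_group samples per (model, timepoint) cell.
#' @param timepoints ordered timepoint labels.
#' @param de_fraction proportion of probes that are DE, in [0, 1].
#' @param effect_sd standard deviation (log2 units) of DE effects.
#' @param rho_per_timepoint correlation in [-1, 1] between the two models'
#'   effect vectors, one value per timepoint (recycled if length 1).
#' @param noise_sd residual Gaussian sd on the log2 scale.
#' @param baseline_range interval for per-probe baseline means (log2 scale).
#' @param seed integer seed; the same design gives bit-identical output.
#' @return an object of class `synthetic_design` (a validated list).
#' @export
synthetic_design <- function(n_probes = 10000,
                             probes_per_gene = 1.5,
                             n_control = 10,
                             n_per_group = 4,
                             timepoints = c("2h", "1d", "3d"),
                             de_fraction = 0.2,
                             effect_sd = 1,
                             rho_per_timepoint = c("2h" = 0.6, "1d" = 0.4, "3d" = -0.3),
                             noise_sd = 0.25,
                             baseline_range = c(4, 14),
                             seed = 1L) {
  stopifnot(n_probes >= 1, n_control >= 1, n_per_group >= 1,
            length(timepoints) >= 1, effect_sd >= 0, noise_sd >= 0,
            length(baseline_range) == 2, baseline_range[1] <= baseline_range[2])
  if (n_probes != round(n_probes) || n_control != round(n_control) ||
      n_per_group != round(n_per_group)) {
    stop("group sizes and probe counts must be whole numbers")
  }
  if (de_fraction < 0 || de_fraction > 1) {
    stop("de_fraction must lie in [0, 1]")
  }
  if (length(rho_per_timepoint) == 1L) {
    rho_per_timepoint <- rep(rho_per_timepoint, length(timepoints))
  } else if (!is.null(names(rho_per_timepoint)) &&
             all(timepoints %in% names(rho_per_timepoint))) {
    rho_per_timepoint <- rho_per_timepoint[as.character(timepoints)]
  }
  if (length(rho_per_timepoint) != length(timepoints)) {
    stop("rho_per_timepoint must have one value per timepoint")
  }
  if (any(abs(rho_per_timepoint) > 1)) {
    stop("each rho_per_timepoint must lie in [-1, 1]")
  }
  names(rho_per_timepoint) <- timepoints
  design <- list(n_probes = as.integer(n_probes),
                 probes_per_gene = probes_per_gene,
                 n_control = as.integer(n_control),
                 n_per_group = as.integer(n_per_group),
                 timepoints = as.character(timepoints),
                 de_fraction = de_fraction,
                 effect_sd = effect_sd,
                 rho_per_timepoint = rho_per_timepoint,
                 noise_sd = noise_sd,
                 baseline_range = baseline_range,
                 seed = as.integer(seed))
  class(design) <- "synthetic_design"
  design
}

probe_gene_map <- function(n_probes, probes_per_gene) {
  if (probes_per_gene == 1.5) {
    block <- rep(seq_len(n_probes), times = rep(c(1L, 2L), length.out = n_probes))
  } else {
    k <- as.integer(probes_per_gene)
    stopifnot(k >= 1)
    block <- rep(seq_len(n_probes), each = k)
  }
  gene_idx <- block[seq_len(n_probes)]
  sprintf("Gene%05d", gene_idx)
}

#' Generate a synthetic expression dataset with known truth
#'
#' Draws a log2 expression matrix (probe sets x samples) under the design:
#' per-probe baselines uniform on `baseline_range`, control values =
#' baseline + noise, septic values = baseline + model/timepoint effect +
#' noise. Effects for DE probes are bivariate normal across the two models
#' with the design's per-timepoint correlation; non-DE effects are exactly 0.
#'
#' @param design a [synthetic_design()].
#' @return a list with components
#'   \describe{
#'     \item{expr}{numeric matrix, probes x samples, log2 scale.}
#'     \item{samples}{data.frame with `sample_id`, `class_label`
#'       (control / modelA / modelB) and `timepoint` (NA for controls).}
#'     \item{probes}{data.frame with `probe_id` and `gene_symbol`.}
#'     \item{truth}{list: `de_flags` (logical per probe), `effect_a` and
#'       `effect_b` (probes x timepoints log2 effect matrices),
#'       `realized_rho` (empirical correlation of the two models' effect
#'       vectors over DE probes, per timepoint), `baseline`.}
#'   }
#' @export
generate_dataset <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  set.seed(design$seed)
  np <- design$n_probes
  tps <- design$timepoints
  nt <- length(tps)

  probe_ids <- sprintf("probe%05d_at", seq_len(np))
  gene_symbol <- probe_gene_map(np, design$probes_per_gene)

  n_de <- round(design$de_fraction * np)
  de_flags <- rep(FALSE, np)
  if (n_de > 0) de_flags[sample.int(np, n_de)] <- TRUE

  effect_a <- matrix(0, np, nt, dimnames = list(probe_ids, tps))
  effect_b <- matrix(0, np, nt, dimnames = list(probe_ids, tps))
  realized_rho <- rep(NA_real_, nt)
  names(realized_rho) <- tps
  for (j in seq_len(nt)) {
    if (n_de == 0) next
    rho <- design$rho_per_timepoint[[j]]
    z1 <- stats::rnorm(n_de)
    z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n_de)
    effect_a[de_flags, j] <- design$effect_sd * z1
    effect_b[de_flags, j] <- design$effect_sd * z2
    if (n_de >= 3) {
      realized_rho[j] <- stats::cor(effect_a[de_flags, j], effect_b[de_flags, j])
    }
  }

  baseline <- stats::runif(np, design$baseline_range[1], design$baseline_range[2])

  ctrl_ids <- sprintf("ctrl_%02d", seq_len(design$n_control))
  grp <- expand.grid(rep = seq_len(design$n_per_group), timepoint = tps,
                     model = c("modelA", "modelB"),
                     stringsAsFactors = FALSE)
  septic_ids <- sprintf("%s_%s_%02d", grp$model, grp$timepoint, grp$rep)
  sample_ids <- c(ctrl_ids, septic_ids)
  samples <- data.frame(
    sample_id = sample_ids,
    class_label = c(rep("control", design$n_control), grp$model),
    timepoint = c(rep(NA_character_, design$n_control), grp$timepoint),
    stringsAsFactors = FALSE)

  expr <- matrix(NA_real_, np, length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (i in seq_along(sample_ids)) {
    cls <- samples$class_label[i]
    delta <- if (cls == "control") {
      0
    } else {
      eff <- if (cls == "modelA") effect_a else effect_b
      eff[, samples$timepoint[i]]
    }
    expr[, i] <- baseline + delta + stats::rnorm(np, 0, design$noise_sd)
  }

  list(expr = expr,
       samples = samples,
       probes = data.frame(probe_id = probe_ids, gene_symbol = gene_symbol,
                           stringsAsFactors = FALSE),
       truth = list(de_flags = stats::setNames(de_flags, probe_ids),
                    effect_a = effect_a, effect_b = effect_b,
                    realized_rho = realized_rho,
                    baseline = stats::setNames(baseline, probe_ids)),
       design = design)
}

#' Generate a dataset where the two models perturb different numbers of probes
#'
#' Companion generator for studying perturbation breadth: each model gets its
#' own independently sampled DE probe set (sizes `de_count_a`, `de_count_b`)
#' with independent N(0, effect_sd^2) log2 effects per timepoint. This mirrors
#' the situation where one sepsis model alters several-fold more genes than
#' the other, the regime the distance-from-reference score is built to rank.
#'
#' @param n_probes,n_control,n_per_group,timepoints,effect_sd,noise_sd,baseline_range,seed
#'   as in [synthetic_design()].
#' @param de_count_a,de_count_b number of DE probes for model A / model B.
#' @return same structure as [generate_dataset()]; `truth` carries per-model
#'   flags `de_a`, `de_b` instead of a shared `de_flags`.
#' @export
generate_asymmetric_dataset <- function(n_probes = 5000,
                                        de_count_a = 500,
                                        de_count_b = 1500,
                                        n_control = 10,
                                        n_per_group = 4,
                                        timepoints = "2h",
                                        effect_sd = 1,
                                        noise_sd = 0.25,
                                        baseline_range = c(4, 14),
                                        seed = 1L) {
  stopifnot(de_count_a <= n_probes, de_count_b <= n_probes,
            de_count_a >= 0, de_count_b >= 0)
  set.seed(seed)
  tps <- as.character(timepoints)
  nt <- length(tps)
  probe_ids <- sprintf("probe%05d_at", seq_len(n_probes))
  gene_symbol <- probe_gene_map(n_probes, 1.5)

  de_a <- rep(FALSE, n_probes); de_a[sample.int(n_probes, de_count_a)] <- TRUE
  de_b <- rep(FALSE, n_probes); de_b[sample.int(n_probes, de_count_b)] <- TRUE
  effect_a <- matrix(0, n_probes, nt, dimnames = list(probe_ids, tps))
  effect_b <- matrix(0, n_probes, nt, dimnames = list(probe_ids, tps))
  for (j in seq_len(nt)) {
    effect_a[de_a, j] <- stats::rnorm(de_count_a, 0, effect_sd)
    effect_b[de_b, j] <- stats::rnorm(de_count_b, 0, effect_sd)
  }

  baseline <- stats::runif(n_probes, baseline_range[1], baseline_range[2])
  ctrl_ids <- sprintf("ctrl_%02d", seq_len(n_control))
  grp <- expand.grid(rep = seq_len(n_per_group), timepoint = tps,
                     model = c("modelA", "modelB"), stringsAsFactors = FALSE)
  septic_ids <- sprintf("%s_%s_%02d", grp$model, grp$timepoint, grp$rep)
  sample_ids <- c(ctrl_ids, septic_ids)
  samples <- data.frame(
    sample_id = sample_ids,
    class_label = c(rep("control", n_control), grp$model),
    timepoint = c(rep(NA_character_, n_control), grp$timepoint),
    stringsAsFactors = FALSE)

  expr <- matrix(NA_real_, n_probes, length(sample_ids),
                 dimnames = list(probe_ids, sample_ids))
  for (i in seq_along(sample_ids)) {
    cls <- samples$class_label[i]
    delta <- if (cls == "control") {
      0
    } else if (cls == "modelA") {
      effect_a[, samples$timepoint[i]]
    } else {
      effect_b[, samples$timepoint[i]]
    }
    expr[, i] <- baseline + delta + stats::rnorm(n_probes, 0, noise_sd)
  }

  list(expr = expr, samples = samples,
       probes = data.frame(probe_id = probe_ids, gene_symbol = gene_symbol,
                           stringsAsFactors = FALSE),
       truth = list(de_a = stats::setNames(de_a, probe_ids),
                    de_b = stats::setNames(de_b, probe_ids),
                    effect_a = effect_a, effect_b = effect_b,
                    baseline = stats::setNames(baseline, probe_ids)))
}

#' Write a generated dataset to the pipeline's standard on-disk inputs
#'
#' Emits the expression matrix (TSV, probes in rows), the sample sheet (CSV),
#' the probe annotation (TSV) and, when truth is present, a truth TSV with
#' per-probe DE flags and effects.
#'
#' @param dataset result of [generate_dataset()] or
#'   [generate_asymmetric_dataset()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named vector of file paths written.
#' @export
write_dataset <- function(dataset, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(expression = file.path(dir, "expression.tsv"),
             samples = file.path(dir, "samples.csv"),
             probes = file.path(dir, "probes.tsv"),
             truth = file.path(dir, "truth.tsv"))
  write_expression(dataset$expr, paths[["expression"]])
  utils::write.csv(dataset$samples, paths[["samples"]], row.names = FALSE, na = "")
  utils::write.table(dataset$probes, paths[["probes"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  tr <- dataset$truth
  if (!is.null(tr)) {
    flags <- if (!is.null(tr$de_flags)) data.frame(de = tr$de_flags)
             else data.frame(de_a = tr$de_a, de_b = tr$de_b)
    tdf <- cbind(data.frame(probe_id = rownames(dataset$expr)), flags,
                 stats::setNames(as.data.frame(tr$effect_a),
                                 paste0("effect_a_", colnames(tr$effect_a))),
                 stats::setNames(as.data.frame(tr$effect_b),
                                 paste0("effect_b_", colnames(tr$effect_b))))
    utils::write.table(tdf, paths[["truth"]], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    paths <- paths[names(paths) != "truth"]
  }
  invisible(paths)
}
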