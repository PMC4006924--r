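#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis. Either provide input
#' file paths (`expression`, `samples`, `probes`, optionally `gene_sets`) or
#' a `simulate` list of [synthetic_design()] arguments to generate inputs.
#'
#' @param expression,samples,probes,gene_sets input file paths (or NULL).
#' @param simulate NULL, or a list of arguments for [synthetic_design()].
#' @param class_map label mapping for the sample sheet.
#' @param cv_threshold,cv_scale unsupervised filter settings.
#' @param alpha F-test selection threshold.
#' @param fold_threshold inclusion cut for activation scoring.
#' @param universe_rule `"union"` or `"intersection"` for the concordance
#'   probe universe.
#' @param dfr_variant `"squared"` or `"abs"`.
#' @param reselect_per_fold,n_permutations LOOCV settings.
#' @param run_prediction logical; permutation LOOCV is the slow stage and can
#'   be disabled.
#' @param seed integer seed for every stochastic stage.
#' @param out_dir output directory, or NULL to skip writing.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(expression = NULL, samples = NULL, probes = NULL,
                            gene_sets = NULL, simulate = NULL,
                            class_map = default_class_map(),
                            cv_threshold = 0.5, cv_scale = "linear",
                            alpha = 0.001, fold_threshold = 2,
                            universe_rule = "union",
                            dfr_variant = "squared",
                            reselect_per_fold = TRUE,
                            n_permutations = 1000,
                            run_prediction = TRUE,
                            seed = 1L, out_dir = NULL) {
  stopifnot(cv_threshold >= 0, alpha > 0, alpha < 1, fold_threshold >= 1,
            n_permutations >= 1, is.numeric(seed))
  if (is.null(simulate) && (is.null(expression) || is.null(samples) || is.null(probes))) {
    stop("provide input paths or a simulate block")
  }
  cfg <- list(expression = expression, samples = samples, probes = probes,
              gene_sets = gene_sets, simulate = simulate,
              class_map = class_map,
              cv_threshold = cv_threshold, cv_scale = cv_scale,
              alpha = alpha, fold_threshold = fold_threshold,
              universe_rule = universe_rule, dfr_variant = dfr_variant,
              reselect_per_fold = reselect_per_fold,
              n_permutations = n_permutations,
              run_prediction = run_prediction,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#' @param path YAML file whose keys mirror [pipeline_config()] arguments.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

# hash of the analysis-relevant settings (output location excluded)
config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  cfg <- unclass(cfg)
  cfg$out_dir <- NULL
  writeLines(yaml::as.yaml(cfg), tmp)
  unname(tools::md5sum(tmp))
}

#' Run the full model-comparison pipeline
#'
#' Stages, mirroring the study's analyses: (1) load or simulate inputs;
#' (2) unsupervised CV filter with hierarchical ordering of the retained
#' probes; (3) supervised F-test selections — pooled three-class and
#' per-model — with gene collapsing and overlap accounting; (4) cross-model
#' concordance (per-timepoint and maximum-change Pearson r) on the combined
#' significant universe (union and intersection both computed); (5) DFR
#' perturbation scores per sample and group on each model's own significant
#' set; (6) optional LOOCV class prediction with a Monte-Carlo permutation
#' null; (7) optional gene-set enrichment/activation table per model and
#' timepoint. Every output table carries the config hash and seed in the
#' run manifest.
#'
#' @param cfg a `pipeline_config`.
#' @return a report bundle (named list); written as TSV/JSON under
#'   `cfg$out_dir` when set.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!is.null(cfg$simulate)) {
    design <- do.call(synthetic_design,
                      c(cfg$simulate, if (!("seed" %in% names(cfg$simulate)))
                        list(seed = cfg$seed)))
    ds <- generate_dataset(design)
    expr <- ds$expr; samples <- ds$samples; probes <- ds$probes
    truth <- ds$truth
  } else {
    expr <- read_expression(cfg$expression)
    samples <- read_sample_annotation(cfg$samples, cfg$class_map, expr = expr)
    probes <- read_probe_annotation(cfg$probes, expr = expr)
    truth <- NULL
  }
  samples <- samples[match(colnames(expr), samples$sample_id), , drop = FALSE]
  timepoints <- unique(samples$timepoint[!is.na(samples$timepoint)])

  bundle <- list(config = cfg, seed = cfg$seed, config_hash = config_hash(cfg))

  # unsupervised stage
  cv_sel <- cv_filter(expr, cfg$cv_threshold, cfg$cv_scale, probes = probes)
  bundle$cv <- list(n_probes = cv_sel$n_probes, n_genes = cv_sel$n_genes,
                    selection = cv_sel)
  if (cv_sel$n_probes >= 2) {
    bundle$cv$ordering <- cluster_order(expr, cv_sel$kept)
  }

  # supervised stage
  three_class <- f_test_selection(expr, samples, "three_class", cfg$alpha, probes)
  per_model <- lapply(c(modelA = "modelA", modelB = "modelB"), function(m) {
    ids <- samples$sample_id[samples$class_label %in% c("control", m)]
    f_test_selection(expr, samples, "model_time", cfg$alpha, probes,
                     subset_samples = ids)
  })
  bundle$selection <- list(three_class = three_class, per_model = per_model,
                           overlap = collapse_and_overlap(per_model$modelA,
                                                          per_model$modelB, probes))

  # concordance stage (both universe rules, flagged)
  if (length(timepoints) >= 1) {
    for (rule in c("union", "intersection")) {
      cu <- list(universe = if (rule == "union") {
        union(per_model$modelA$kept, per_model$modelB$kept)
      } else {
        intersect(per_model$modelA$kept, per_model$modelB$kept)
      }, rule = rule)
      key <- paste0("concordance_", rule)
      if (length(cu$universe) >= 3) {
        bundle[[key]] <- concordance_report(expr, samples, cu$universe, timepoints)
        bundle[[key]]$rule <- rule
      } else {
        bundle[[key]] <- list(skipped = TRUE,
                              reason = sprintf("only %d probe(s) in %s universe",
                                               length(cu$universe), rule))
        message("concordance (", rule, ") skipped: ", bundle[[key]]$reason)
      }
    }
    bundle$concordance <- bundle[[paste0("concordance_", cfg$universe_rule)]]
  }

  # DFR stage: each model scored on its own significant set
  bundle$dfr <- lapply(c(modelA = "modelA", modelB = "modelB"), function(m) {
    sel <- per_model[[m]]$kept
    if (length(sel) < 1) {
      message("DFR for ", m, " skipped: empty significant set")
      return(list(skipped = TRUE, reason = "empty significant set"))
    }
    ref <- build_reference(expr, samples, sel)
    ids <- samples$sample_id[samples$class_label %in% c("control", m)]
    list(reference_n_probes = length(ref$universe),
         scores = dfr_scores(expr[, ids, drop = FALSE], ref, cfg$dfr_variant),
         groups = group_dfr(expr[, ids, drop = FALSE],
                            samples[samples$sample_id %in% ids, , drop = FALSE],
                            ref, cfg$dfr_variant))
  })

  # class prediction stage
  if (isTRUE(cfg$run_prediction)) {
    bundle$prediction <- permutation_pvalue(
      expr, samples, selector_alpha = cfg$alpha,
      reselect_per_fold = cfg$reselect_per_fold,
      n_permutations = cfg$n_permutations, seed = cfg$seed)
  }

  # gene-set stage
  if (!is.null(cfg$gene_sets)) {
    sets <- read_gene_sets(cfg$gene_sets)
    universe <- unique(probes$gene_symbol[!is.na(probes$gene_symbol)])
    bundle$genesets <- lapply(c(modelA = "modelA", modelB = "modelB"), function(m) {
      sig_genes <- unique(stats::na.omit(
        probes$gene_symbol[match(per_model[[m]]$kept, probes$probe_id)]))
      lapply(stats::setNames(timepoints, timepoints), function(tp) {
        prof <- change_profile(expr, samples, m, tp)
        geneset_table(sets, sig_genes, universe,
                      gene_folds = gene_changes(prof, probes),
                      fold_threshold = cfg$fold_threshold)
      })
    })
  }

  bundle$truth <- truth
  if (!is.null(cfg$out_dir)) write_bundle(bundle, cfg$out_dir)
  bundle
}

write_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wt <- function(df, name) {
    utils::write.table(df, file.path(dir, name), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  ov <- bundle$selection$overlap$counts
  wt(data.frame(stage = c("cv_filter", "f_test_three_class",
                          "modelA", "modelB", "overlap_genes"),
                probes = c(bundle$cv$n_probes,
                           bundle$selection$three_class$n_probes,
                           bundle$selection$per_model$modelA$n_probes,
                           bundle$selection$per_model$modelB$n_probes,
                           ov[["probes_common"]]),
                genes = c(bundle$cv$n_genes,
                          bundle$selection$three_class$n_genes,
                          bundle$selection$per_model$modelA$n_genes,
                          bundle$selection$per_model$modelB$n_genes,
                          ov[["genes_common"]])),
     "selection_counts.tsv")
  if (!is.null(bundle$concordance) && is.null(bundle$concordance$skipped)) {
    cc <- bundle$concordance
    wt(rbind(cc$per_timepoint,
             data.frame(timepoint = "max_change", r = cc$max_change$r,
                        p = cc$max_change$p, n = cc$max_change$n)),
       "concordance.tsv")
  }
  for (m in names(bundle$dfr)) {
    if (is.null(bundle$dfr[[m]]$skipped)) {
      wt(bundle$dfr[[m]]$groups, paste0("dfr_groups_", m, ".tsv"))
    }
  }
  if (!is.null(bundle$prediction)) {
    pr <- bundle$prediction
    wt(pr$calls, "prediction_calls.tsv")
    wt(data.frame(observed_rate = pr$observed_rate, p_value = pr$p_value,
                  n_permutations = pr$n_permutations),
       "prediction_summary.tsv")
  }
  if (!is.null(bundle$genesets)) {
    for (m in names(bundle$genesets)) {
      for (tp in names(bundle$genesets[[m]])) {
        wt(bundle$genesets[[m]][[tp]],
           sprintf("genesets_%s_%s.tsv", m, tp))
      }
    }
  }
  if (!is.null(bundle$cv$ordering)) {
    writeLines(bundle$cv$ordering$probe_order, file.path(dir, "heatmap_probe_order.txt"))
    writeLines(bundle$cv$ordering$sample_order, file.path(dir, "heatmap_sample_order.txt"))
  }
  manifest <- list(config_hash = bundle$config_hash, seed = bundle$seed,
                   stages = names(bundle))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}
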