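#!/usr/bin/env Rscript
# Gene selection: the unsupervised CV > 0.5 filter (linear scale), the
# pooled three-class F test, and per-model F tests versus control at
# p < 0.001, with probe-set -> gene collapsing and overlap accounting.

library(sepsisconcord)

expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_annotation("results/data/samples.csv", expr = expr)
probes <- read_probe_annotation("results/data/probes.tsv", expr = expr)

cv <- cv_filter(expr, threshold = 0.5, scale = "linear", probes = probes)
cat(sprintf("CV > 0.5 retains %d probe sets (%d genes)\n",
            cv$n_probes, cv$n_genes))

three <- f_test_selection(expr, samples, "three_class", 0.001, probes)
cat(sprintf("three-class F test, p < 0.001: %d probe sets (%d genes)\n",
            three$n_probes, three$n_genes))

per_model <- lapply(c(modelA = "modelA", modelB = "modelB"), function(m) {
  ids <- samples$sample_id[samples$class_label %in% c("control", m)]
  f_test_selection(expr, samples, "model_time", 0.001, probes,
                   subset_samples = ids)
})
ov <- collapse_and_overlap(per_model$modelA, per_model$modelB, probes)
cat(sprintf("model A: %d probe sets (%d genes); model B: %d probe sets (%d genes)\n",
            per_model$modelA$n_probes, per_model$modelA$n_genes,
            per_model$modelB$n_probes, per_model$modelB$n_genes))
cat(sprintf("overlap: %d probe sets, %d genes (%d unique to A, %d unique to B)\n",
            ov$counts[["probes_common"]], ov$counts[["genes_common"]],
            ov$counts[["genes_only_a"]], ov$counts[["genes_only_b"]]))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(data.frame(stage = c("cv_filter", "f_three_class", "modelA",
                                 "modelB", "overlap"),
                       probes = c(cv$n_probes, three$n_probes,
                                  per_model$modelA$n_probes,
                                  per_model$modelB$n_probes,
                                  ov$counts[["probes_common"]]),
                       genes = c(cv$n_genes, three$n_genes,
                                 per_model$modelA$n_genes,
                                 per_model$modelB$n_genes,
                                 ov$counts[["genes_common"]])),
            "results/tables/selection_counts.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
writeLines(per_model$modelA$kept, "results/tables/significant_probes_modelA.txt")
writeLines(per_model$modelB$kept, "results/tables/significant_probes_modelB.txt")

ord <- cluster_order(expr, cv$kept)
writeLines(ord$sample_order, "results/tables/heatmap_sample_order.txt")
cat("sample dendrogram order:", paste(head(ord$sample_order, 8), collapse = " "),
    "...\n")
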