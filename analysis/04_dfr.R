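#!/usr/bin/env Rscript
# Distance-from-reference (DFR) perturbation score: each sample's
# variance-normalized squared deviation from the healthy-control reference,
# summed over the model's own significant probes and reduced to ln(D).
# Group means with SEM per model and timepoint, controls as the baseline.

library(sepsisconcord)

expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_annotation("results/data/samples.csv", expr = expr)

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
for (m in c("modelA", "modelB")) {
  ids <- samples$sample_id[samples$class_label %in% c("control", m)]
  sel <- f_test_selection(expr, samples, "model_time", 0.001,
                          subset_samples = ids)
  ref <- build_reference(expr, samples, sel$kept)
  g <- group_dfr(expr[, ids, drop = FALSE],
                 samples[samples$sample_id %in% ids, ], ref)
  cat(sprintf("\n%s (reference over %d significant probe sets):\n",
              m, length(ref$universe)))
  print(g, row.names = FALSE, digits = 4)
  write.table(g, sprintf("results/tables/dfr_groups_%s.tsv", m),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
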