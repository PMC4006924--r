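#!/usr/bin/env Rscript
# Class prediction: can the transcriptome identify which sepsis model (or
# control) a sample came from? Leave-one-out cross-validation with
# nearest-centroid classification on per-fold F-test-selected probes, and a
# Monte-Carlo permutation null for the misclassification rate.

library(sepsisconcord)

expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_annotation("results/data/samples.csv", expr = expr)

res <- permutation_pvalue(expr, samples, selector_alpha = 0.001,
                          reselect_per_fold = TRUE,
                          n_permutations = 1000, seed = 20140501)
cat(sprintf("observed LOOCV misclassification: %.3f (%d/%d samples)\n",
            res$observed_rate,
            sum(res$calls$predicted != res$calls$true), nrow(res$calls)))
cat(sprintf("permutation null: median rate %.3f over B = %d\n",
            median(res$null_rates), res$n_permutations))
cat(sprintf("p = %.4g -> the class labels are %sidentifiable from expression\n",
            res$p_value, if (res$p_value < 0.01) "" else "not clearly "))

dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(res$calls, "results/tables/prediction_calls.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
write.table(data.frame(observed_rate = res$observed_rate,
                       p_value = res$p_value,
                       n_permutations = res$n_permutations),
            "results/tables/prediction_summary.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
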