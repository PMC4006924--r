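#!/usr/bin/env Rscript
# Cross-model concordance: Pearson correlation between the two models' mean
# log2 changes versus control per timepoint, and the maximum-change
# correlation over time, on the union of the significant probe sets.

library(sepsisconcord)

expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_annotation("results/data/samples.csv", expr = expr)

for (rule in c("union", "intersection")) {
  cu <- concordance_universe(expr, samples, alpha = 0.001, rule = rule)
  cc <- concordance_report(expr, samples, cu$universe,
                           timepoints = c("2h", "1d", "3d"))
  cat(sprintf("\n%s universe (%d probe sets):\n", rule, length(cu$universe)))
  for (i in seq_len(nrow(cc$per_timepoint))) {
    cat(sprintf("  %-3s r = %+.3f (p = %.3g, n = %d)\n",
                cc$per_timepoint$timepoint[i], cc$per_timepoint$r[i],
                cc$per_timepoint$p[i], cc$per_timepoint$n[i]))
  }
  cat(sprintf("  max-change r = %+.3f (r^2 = %.3f)\n",
              cc$max_change$r, cc$max_change$r2))
  if (rule == "union") {
    dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
    write.table(rbind(cc$per_timepoint,
                      data.frame(timepoint = "max_change", r = cc$max_change$r,
                                 p = cc$max_change$p, n = cc$max_change$n)),
                "results/tables/concordance.tsv",
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
}
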