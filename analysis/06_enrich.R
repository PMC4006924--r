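#!/usr/bin/env Rscript
# Gene-set statistics: Fisher over-representation (-log10 p, the p = 0.05
# line at 1.3) of each model's significant genes, and the directional
# activation Z-score over genes passing the two-fold-change rule, |Z| >= 2
# flagged significant. Demonstrated on synthetic direction-annotated sets
# built from the simulation truth: an "activated" set drawn from genes the
# generator perturbed (directions set to the true signs at 2 h) and a
# "background" set of unperturbed genes.

library(sepsisconcord)

expr <- read_expression("results/data/expression.tsv")
samples <- read_sample_annotation("results/data/samples.csv", expr = expr)
probes <- read_probe_annotation("results/data/probes.tsv", expr = expr)
truth <- read.delim("results/data/truth.tsv")

# synthetic gene sets from truth: perturbed vs unperturbed genes for model B
de_genes <- unique(na.omit(probes$gene_symbol[match(
  truth$probe_id[truth$de], probes$probe_id)]))
bg_genes <- setdiff(unique(na.omit(probes$gene_symbol)), de_genes)
set.seed(1)
pick <- sample(de_genes, 40)
dirs <- sapply(pick, function(g) {
  pr <- probes$probe_id[which(probes$gene_symbol == g)[1]]
  sign(truth$effect_b_2h[truth$probe_id == pr])
})
pick <- pick[dirs != 0]; dirs <- dirs[dirs != 0]
sets <- list(
  activated = list(name = "activated", genes = pick,
                   directions = setNames(dirs, pick)),
  background = list(name = "background", genes = sample(bg_genes, 40),
                    directions = NULL))
gmt <- "results/data/sets.gmt"
write_gene_sets(sets, gmt)

ids <- samples$sample_id[samples$class_label %in% c("control", "modelB")]
sel <- f_test_selection(expr, samples, "model_time", 0.001, probes,
                        subset_samples = ids)
sig_genes <- unique(na.omit(probes$gene_symbol[match(sel$kept, probes$probe_id)]))
universe <- unique(na.omit(probes$gene_symbol))
prof <- change_profile(expr, samples, "modelB", "2h")
tab <- geneset_table(read_gene_sets(gmt), sig_genes, universe,
                     gene_folds = gene_changes(prof, probes),
                     fold_threshold = 2)
print(tab, row.names = FALSE, digits = 4)
cat(sprintf("\n'activated' set: -log10 p = %.2f (1.3 marks p = 0.05), Z = %.2f%s\n",
            tab$minus_log10_p[tab$set == "activated"],
            tab$z[tab$set == "activated"],
            if (isTRUE(tab$significant_z[tab$set == "activated"]))
              " (|Z| >= 2: significant)" else ""))
dir.create("results/tables", showWarnings = FALSE, recursive = TRUE)
write.table(tab, "results/tables/genesets_modelB_2h.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
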