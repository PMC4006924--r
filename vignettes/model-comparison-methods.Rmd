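---
title: "Methods: comparing sepsis models at the leukocyte transcriptome level"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparing sepsis models at the leukocyte transcriptome level}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sepsisconcord)
```

## The scientific problem

Murine models of polymicrobial intra-abdominal sepsis — cecal ligation and
puncture (CLP), where a ligated, punctured cecum provides a persistent
infectious nidus, and cecal slurry (CS), a bolus intraperitoneal injection of
donor cecal contents — are often treated as interchangeable. This package
implements a transcriptome-level comparison of two such models against a
shared healthy-control group: are the blood-leukocyte expression programs the
two models induce actually concordant, and how far does each push a sample
away from the healthy state?

The pipeline consumes an RMA-style normalized log2 expression matrix (probe
sets × samples), a sample sheet assigning each sample a class (control,
model A, model B) and, for septic samples, a timepoint (2 h, 1 d, 3 d by
default), and a probe-set → gene-symbol annotation. Every analysis stage is
also exercisable on synthetic cohorts with known ground truth.

## Stages and their statistics

**Unsupervised filter.** The coefficient of variation sd/mean is computed
per probe on the *linear* intensity scale (values anti-logged as `2^x`)
and probes with CV > 0.5 are retained. The linear scale is the default
because on log2-scale normalized data — where typical values sit around
4–14 with residual sd well under 1 — a CV > 0.5 cut would retain almost
nothing; on the linear scale it retains the substantially varying fraction
of the array, which is how such filters are conventionally applied. A
`log2` option is kept for sensitivity analysis. Retained probes and the
samples are ordered by average-linkage hierarchical clustering on
1 − Pearson correlation distance for heat-map export; ties follow input
order and constant probes (undefined correlation) are placed last, so the
ordering is deterministic.

**Supervised selection.** A per-probe one-way ANOVA F test across either
the three classes (timepoints pooled) or the control-plus-(model ×
timepoint) cells; probes with raw p < 0.001 are selected, with no
multiple-testing correction — the raw cut *is* the selection rule this
analysis style uses — though a Benjamini–Hochberg FDR column is emitted for
reference. Both groupings are reported: the pooled test mirrors the overall
"sepsis responsive" contrast, the stratified one underlies per-model gene
lists. Zero within-group variance (possible only with degenerate input)
yields p = 0 with a warning. Gene-level counts collapse probe sets by
symbol, a gene being significant when at least one of its probe sets is;
probes without a symbol stay in probe-level statistics but are excluded
from gene collapsing.

**Fold changes.** Per probe, the mean log2 change d of a (model, timepoint)
group versus the control mean, and the reciprocal-convention signed fold:
2^d for d ≥ 0, −2^(−d) otherwise, so a halving is −2 and |fold| ≥ 1 always.
Correlations are always computed on log2 changes, never on signed folds.

**Cross-model concordance.** For each timepoint, the Pearson correlation
(with the usual t-transform two-sided p) between model A's and model B's
log2 change vectors over a selected probe universe; additionally the
correlation of the two *maximum-change* vectors, where each probe
contributes its largest-|d| change across timepoints with sign retained
(ties to the earliest timepoint). The default universe is the **union** of
the two models' significant sets: an intersection-only universe discards
model-unique responders, which are precisely where the models disagree, and
so inflates r. Both rules are computed and flagged in the report.

Two numerical caveats the synthetic experiments make visible. First,
because both models' changes subtract the *same* control mean, shared
control noise induces a baseline positive correlation of roughly
(1/n_c)/(1/n_g + 1/n_c) even between models with independent (ρ = 0)
effects; with 10 controls and groups of 4 that is ≈ 0.29 on a pure-noise
universe. On a universe of genuinely responsive probes the effect-driven
variance dominates and the bias is negligible — one more reason the
correlation is computed on significant probes rather than genome-wide.
Second, noise attenuates |r| by a factor σ²_eff/(σ²_eff + σ²_noise·(1/n_g +
1/n_c)); at the default settings this is under 3 %.

**Distance from reference (DFR).** The control reference holds, per probe,
the control mean M_i and unbiased (n − 1) variance V_i; zero-variance
probes are excluded. A sample with expression e_i over a significant-probe
universe of size G scores the raw distance

D = Σ_i (e_i − M_i)² / V_i,

reported on the natural-log scale as dfr = ln D. The squared,
variance-normalized form is used because only it makes D non-negative and
additive over probe subsets; an |e−M|/√V variant is available behind a
flag for sensitivity analysis. D = 0 (a sample identical to the reference
mean) is flagged degenerate rather than log-transformed. Each model is
scored on its *own* significant set by default — the score asks "how far
has this model moved the genes it moves" — with a shared-universe option
for equal-footing comparisons. For a sample drawn from the control
population itself, E[D/G] = (1 + 1/n)(n − 1)/(n − 3) (each term is a
scaled F statistic); at n = 10 controls that is ≈ 1.414, the calibration
the tests verify. Group summaries report mean ± SEM per (class, timepoint),
the control group's own mean serving as the baseline; SEM is NA for groups
of one.

**Class prediction.** Leave-one-out cross-validation of a nearest-centroid
classifier: per fold, the F-test selection is re-run on the training
samples only (avoiding selection bias; a flag reproduces the optimistic
variant that selects once on all samples), class centroids are computed on
the selected probes, and the held-out sample is assigned the class with the
smallest Euclidean distance standardized by the per-probe pooled
within-class sd. Nearest centroid is used because it is the parameter-free
canonical choice in this class-prediction tradition. When no probe passes
the per-fold cut — common under the null at α = 0.001 — the single
smallest-p probe is used so the classifier is always defined. The
significance of the misclassification rate comes from a Monte-Carlo
permutation null: class labels are permuted jointly across the whole cohort
(controls included), the full LOOCV including reselection is repeated, and
the add-one p-value (1 + #{null rate ≤ observed})/(B + 1) is reported
(never zero; B = 1,000 by default, seedable).

Two properties of this p-value worth knowing. Because LOOCV rates are
discrete, ties between the observed and permuted rates make the p-value
conservative (super-uniform) under the null rather than exactly uniform;
the tests therefore verify validity — P(p ≤ α) ≤ α within Monte-Carlo
error — and central tendency, not strict uniformity. And on a perfectly
separable cohort the floor p = 1/(B + 1) is attained only if no permutation
happens to reproduce the true class partition (any partition-preserving
relabeling also classifies perfectly); with c classes of n samples that
probability is c!·(n!)^c/N! per permutation, which is why the calibration
experiments use at least 5 samples per class.

The fold loop is implemented on incremental sufficient statistics (group
sums and sums of squares with the held-out column subtracted), so the
permutation null stays tractable on genome-scale matrices.

**Gene-set statistics.** In place of proprietary pathway tools, two
documented statistics over user-supplied GMT sets: (i) Fisher's exact
two-sided p for over-representation of a set among significant genes in a
2×2 table against the annotated-gene universe, reported as −log10 p so the
conventional p = 0.05 line sits at 1.3; (ii) a directional activation
Z-score over set genes passing the two-fold-change inclusion rule,
Z = (N_consistent − N_inconsistent)/√N, a gene being consistent when the
sign of its observed fold matches its annotated expected direction
(`SYMBOL|+1` / `SYMBOL|-1` in the GMT dialect), with |Z| ≥ 2 — the
two-sided 95 % normal band — flagged significant. Z = 0 when no gene
passes. Under a random-sign null with N around 30, P(|Z| ≥ 2) ≈ 4.3–4.6 %
(the discrete binomial tail slightly undershoots the normal 4.6 %).

## The synthetic-data generator

`generate_dataset()` draws per-probe baselines uniform on [4, 14] (the
typical normalized log2 intensity range, chosen to exercise the CV filter's
scale behavior), adds, for a designated DE fraction of probes, per-(model,
timepoint) log2 effects drawn bivariate-normally across the two models with
sd `effect_sd` and per-timepoint correlation `rho_per_timepoint`, and
Gaussian log2 noise (sd 0.25 by default, a typical residual scale for
RMA-normalized arrays). Non-DE probes carry *exactly* zero effect — a
sharp null that makes F-test type-I calibration exact. Defaults: 10
controls (a stable DFR reference) and 4 samples per (model, timepoint)
cell; effect correlations (0.6, 0.4, −0.3) across 2 h / 1 d / 3 d,
the decaying-then-inverting concordance pattern the pipeline is designed to
detect; probe sets map to gene symbols in alternating blocks of 1 and 2 so
probe and gene counts differ. `generate_asymmetric_dataset()` instead gives
each model its own independently drawn DE set, for studying perturbation
breadth (e.g. one model altering three times as many genes, the regime the
DFR score ranks).

What the generator does *not* emulate: probe-level intensity-dependent
variance, batch effects, correlated gene modules, or shifts in leukocyte
subset composition. Passing tests therefore demonstrate the statistical
machinery is correct and calibrated under the stated model, not that real
cohorts satisfy that model.

## Problem sizes used in validation

Calibration experiments run at 10,000 probes (F-test null fraction;
realized-ρ recovery within ±0.03; concordance recovery within ±0.05 with
5,000 DE probes), 1,000 probes × 1,000 draws for the DFR null ratio
(±10 %), 100 seeded replicates for the DFR model-ordering check, B = 999
permutations for the separable-cohort p-value and 100 null cohorts at
B = 99 for its validity, and 10,000 draws for the activation-Z tail.
Brute-force oracles (loop-based CV and max-change scans, set algebra,
hypergeometric enumeration for universes ≤ 50, a naive agglomerative
clusterer, an independent LOOCV implementation) are re-run on ≥ 100 random
small instances each.

## Design choices and limitations

* The analysis shape is a scripted workflow (`analysis/01…06`) over an R
  package, because the deliverable is a sequence of analyses on one cohort
  design rather than a shell tool; `run_pipeline()` orchestrates the same
  stages end-to-end from a config (YAML-loadable) with a config hash and
  seed in the run manifest.
* Group sizes per (model, timepoint) are not dictated by the design being
  emulated; 4 per cell and 10 controls are configurable defaults.
* Free-text class labels in sample sheets (e.g. "CLP", "CS") are mapped to
  the three roles via a configurable map, so externally derived sheets load
  unedited.
* Missing values are rejected, not imputed: the expected input is a
  complete post-normalization matrix.
* The activation Z is the simple published form over direction-annotated
  gene sets; it does not attempt any knowledge-base network propagation,
  so its values are comparable only between runs of this pipeline.
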