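---
title: "Module-cluster statistics for single-cell atlases: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Module-cluster statistics for single-cell atlases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

scmodnet implements the downstream statistics of a clustered single-cell
RNA-seq atlas: quality filtering, marker detection, gene-set enrichment,
robust weighted co-expression networks, and two permutation procedures that
link gene modules to cell clusters. This vignette is the package's own
account of those methods — what is computed, under which assumptions, which
parameters matter, and where a genuinely open design choice was settled.

## The analysis model

The input is a cells × genes count matrix with per-cell QC metrics and
per-cell cluster labels. Clustering itself, normalization-by-model
(SCTransform-style), dataset integration and doublet *scoring* are upstream
steps performed by established tools; this package consumes their outputs.
Internally cells always index rows; on disk the 10x convention (genes ×
cells Matrix Market triplet with `genes.tsv`/`barcodes.tsv` sidecars) is
transposed at the boundary.

### Quality filtering

A cell is retained iff it has at least `min_features` (default 500) and at
most `max_features` (default 9,000) detected genes, at most
`max_total_counts` (default 1e5) total counts, a doublet score at or below
the per-sample threshold, and at most `max_pct_mito` (default 10) percent
mitochondrial counts. Removal criteria are stated as strict inequalities
("fewer than 500 features"), so threshold-sitting cells are retained; every
excluded cell carries all reason codes that apply. The count-based defaults
target full-transcriptome data (~20k genes); desk-scale synthetic atlases
(hundreds to a thousand genes) use proportionally scaled values, as the
analysis scripts do.

In place of model-based normalization the package uses plain log
library-size normalization, `log(1 + count × scale_total / cell_total)`
(natural log, `scale_total` 1e4): a deliberate, documented divergence —
normalization by regression model is an upstream published-tool step, and
the downstream statistics only require a monotone, sparsity-preserving,
depth-corrected transform. Variable genes are ranked by the transparent
dispersion statistic variance/mean of the normalized values (ties broken by
gene order, never-expressed genes last); the network stage uses the top
3,000 genes at full scale, 300 at desk scale.

### Marker detection

Two complementary detectors are run:

* **Rank-sum markers.** Per cluster, each gene's normalized expression is
  compared between in-cluster cells and all others with a two-sided
  Wilcoxon rank-sum test. The implementation uses the normal approximation
  with tie correction (no continuity correction), switching to exact
  enumeration of all group assignments below 10 cells; tests verify it
  against `stats::wilcox.test` and an exhaustive enumeration oracle. Only
  up-regulated genes with `avg_logFC ≥ 0.25` are reported, where
  `avg_logFC = log(mean(expm1(in)) + 1) − log(mean(expm1(out)) + 1)`
  (natural log; the pseudocount of 1 is a common convention the upstream
  toolchains leave implicit). BH correction is applied jointly across all
  reported (gene, cluster) records, since the reporting universe is the
  whole screen.
* **Specificity markers.** A gene marks a cluster iff detected
  (raw count > 0) in strictly more than 60% of the cluster's cells and in
  strictly less than 10% of the cells of every other cluster. "Expressed"
  means a nonzero raw count — the detection-fraction semantics of dot-plot
  screening; the rule therefore depends only on the zero pattern and is
  invariant to magnitudes and cell order.

The best single marker per cluster maximizes the margin
`pct_in − pct_out_max` over the pooled candidates, with ties broken by
larger `pct_in` and then lexicographically smaller gene id — deterministic
by construction. The same 60/10 rule generalizes to a census of arbitrary
query genes against a target cluster (`celltype_restricted_genes`).

### Gene-set enrichment

Marker enrichment per cluster uses a one-sided Wilcoxon rank-sum test of a
score vector over the gene universe: each gene scores its marker
`avg_logFC`, 0 if not a marker of that cluster, and each gene set's scores
are compared against the rest of the universe (alternative: greater). The
choice of score and direction is interpretive — the upstream description
names only "a Wilcoxon enrichment test" — and is flagged as such: any
monotone transform of the scores gives identical results, and the type-I
rate is verified on random sets. BH correction is applied within a cluster
across pathways. Module–pathway relationships are reported only as overlap
counts with a ≥ 3-gene floor, explicitly without p-values: module
membership carries no per-gene score on which a rank test would be honest.

### Co-expression network

The network is built on the variable genes from the normalized matrix:

1. **Biweight midcorrelation** (`bicor_matrix`). Observations are
   standardized per gene by `u = (x − median) / (9 · mad)` (scaled MAD) and
   weighted by Tukey biweights `w = (1 − u²)² · 1[|u| < 1]`; the
   correlation is the normalized cross-product of the weighted centered
   vectors. `max_p_outliers` (default 0.05) caps, per side of the median,
   the fraction of observations that can receive zero weight, by rescaling
   a side whose capping quantile passes |u| = 1. Genes with zero MAD
   (majority-zero expression) fall back to Pearson for their pairs and are
   flagged; constant genes get correlation 0 with a flag. The vectorized
   implementation is tested to 1e−10 against a literal loop transcription
   of the formula.
2. **Soft threshold.** Connectivities `k_i = Σ|cor|^β` are fitted for
   scale-free topology (log–log regression of binned degree frequency);
   the analysis uses the explicit override β = 2, the value where the fit
   levels off on the data this workflow models, and the full fit table is
   always written for inspection.
3. **Topological overlap.** Unsigned TOM with the standard normalization
   `(L_ij + a_ij) / (min(k_i, k_j) + 1 − a_ij)`; dissimilarity `1 − TOM`
   feeds average-linkage hierarchical clustering.
4. **Module detection** (`cut_modules`). A simplified dynamic cut: the cut
   height is the midpoint of the largest gap in the sorted merge heights,
   capped by a `deep_split`-mapped quantile (0..4 → 0.95, 0.90, 0.85,
   0.80, 0.75) that restricts how high the gap may start. The gap rule is
   the package's own design choice: on realistic data, average-linkage
   merge heights concentrate in a narrow band near the top of the tree
   (unrelated genes attaching at dissimilarity ≈ 1), so any fixed quantile
   of merge heights lands inside that band and either lumps all modules
   into one branch or dissolves them; the dominant gap, in contrast,
   separates branch-internal merges from the background band exactly where
   planted-structure recovery succeeds, and degenerates gracefully — with
   no gap (all heights equal) nothing is cohesive and every gene is left
   unassigned. Branches below `min_cluster_size` (default 15) go to module
   0 (unassigned); modules are numbered by decreasing size (numbering is
   presentation only). Branch-for-branch parity with the reference
   hybrid tree-cut heuristic is not attempted; the acceptance surface is
   planted-structure recovery.
5. **Eigengenes and merging.** A module eigengene is the first principal
   component over cells of the module's standardized expression — computed
   from expression, not from the adjacency, which is the conventional
   definition — unit-norm, sign-aligned to correlate non-negatively with
   the module mean. Modules whose eigengenes cluster below 0.35
   dissimilarity (1 − correlation, average linkage) are merged and
   eigengenes recomputed, iterating to a fixed point.

The network is unsigned (`|cor|^β`), matching the default behavior of the
reference toolchain when signedness is unstated.

### Module–cluster inference

Both procedures treat the cluster labels as the unit of inference and are
exactly reproducible under a seed.

* **Association.** For each (cluster, module),
  `t = (mean_cluster − mean_all) / (sd_cluster / √n_cluster)` — a
  one-sample t-statistic of the cluster's eigengene scores against the
  whole-atlas mean used as the population reference. The null permutes
  cluster labels over cells (sizes preserved) and recomputes all
  statistics; the default p-value is two-sided
  (`#{|t*| ≥ |t|} / n_perm`). The upstream description calls this a
  "two-way" permutation test without defining the term; two-sided is the
  reading implemented by default, and a one-sided option is exposed. A
  zero-variance cluster with nonzero numerator is recorded as a capped
  sentinel (±1e10) and flagged rather than propagating infinities.
* **Connectivity sensitivity.** Total intramodular connectivity
  `K = Σ_{i≠j∈module} a_ij` is recomputed from expression on each cell
  subset (not rescaled from the full-data adjacency): all cells, then each
  cluster dropped in turn. The null redraws equally sized uniformly random
  drops from all cells — including the focal cluster's, since the
  procedure is described as dropping cells "randomly" without exclusion; a
  restricted pool is exposed as an option. The p-value counts null changes
  *strictly greater* than the observed one, with no +1 smoothing — the
  literal counting rule, preserving exact zeros at strong signals; a
  smoothed `(count + 1)/(n_perm + 1)` option exists for users needing
  nonzero floors. Removal of an uninvolved cluster can *increase* measured
  connectivity (the active cells' share grows), so `K_drop ≤ K_full` is
  deliberately not an invariant; the test is one-sided for
  connectivity-reducing clusters by construction.

Both tables are BH-corrected jointly across all cluster × module pairs of
the procedure (the correction universe is unstated upstream; joint
correction is the conservative screen-wide choice). Permutation counts
default to 1,000; fewer than 100 is rejected as having unusable tail
resolution.

## The synthetic atlas generator

`generate_atlas` emulates exactly the statistical structure the pipeline
assumes, under a single seed:

* **Background**: independent negative-binomial counts (mean
  `baseline_mean`, size `dispersion`). Defaults 0.6 and 2 give the sparse,
  overdispersed regime of droplet data at desk scale (~45% detection per
  gene).
* **Markers**: drawn as Bernoulli(detection fraction) × (1 + NB), so the
  planted in/out detection fractions are *exact* Bernoulli rates — the
  60/10 boundary behavior can be tested without binomial slack — and the
  in-cluster NB mean is inflated by `fold_change`.
* **Modules**: a per-cell latent factor, Normal(0, `factor_sd`) in the
  module's active clusters and exactly 0 elsewhere, enters the log-mean
  with weight `loading` (`mu = baseline_mean · e^{loading·f}`). This
  yields positive within-module correlation visible to bicor after log
  normalization, plus an elevated module mean in active clusters — which
  is what the eigengene t-statistic detects. Gene sets are pairwise
  disjoint; a gene in both a marker and a module plan is rejected outright
  as conflicting cluster structure.
* **Mitochondrial load**: designated mito genes are scaled per cell by a
  log-normal factor calibrated to a ~3% median mitochondrial fraction with
  a minority tail past 10%, so the mito filter has something to remove.
* **Doublets**: appended cells that are exact sums of two random parents'
  count vectors, flagged in the truth. The continuous doublet score is the
  cell's similarity to the doublet population — detected-gene complexity
  (doublets carry the union of two parents' genes) blended 0.7/0.3 with
  cosine similarity to the mean doublet profile, min–max rescaled — so a
  per-sample score threshold behaves like an external caller's.

What the generator does *not* emulate: ambient RNA, batch effects,
UMI-level sampling, gene–gene correlation beyond the planted factors, and
realistic transcriptome-wide mean/dispersion profiles. Passing tests
therefore demonstrate the statistical machinery is correct on data meeting
its assumptions — not that any particular biological dataset meets them.

## Study conditions and problem sizes

The test suite and the reproduction script exercise the pipeline end to end
on a fixed desk-scale condition chosen once: 3,000 cells in 5 equal
clusters, 1,000 genes, five disjoint 25-gene modules each driven by one
cluster (`factor_sd` 1, `loading` 2 — giving median within-module bicor
≈ 0.5 in the active cluster, comfortably above the 0.4 regime where
module recovery is expected), one 90/5 marker per cluster, 4% doublets.
QC thresholds scale to the 1,000-gene atlas (100–950 features, 10% mito,
doublet score 0.5); the network uses 300 variable genes, power 2, minimum
module size 15, merge cutoff 0.35, 1,000 permutations. The bundled
integration fixture is smaller still (800 cells, 300 genes, two 25-gene
modules active in two clusters each) with its own proportional settings —
at a few hundred cells a single-cluster factor contributes too little
global variance for dispersion ranking, so two active clusters per module
is the smallest realistic desk configuration.

## Numerical choices and degenerate inputs

* Correlations are clamped to [−1, 1]; TOM to [0, 1]; the unit diagonal is
  set exactly.
* Zero-total cells normalize to zero rows with a warning (and are removed
  by any sensible `min_features`); zero-variance genes are dropped from
  eigengene PCs with a warning; a module left with fewer than 2 usable
  genes is an error.
* `cutree` boundary: the gap-cut height is strictly below the top merge,
  so a single all-gene module can only arise if it is genuinely cohesive.
* Permutation p-values are literal counts over `n_perm` (optionally
  smoothed); BH is `stats::p.adjust` behind a validating wrapper that
  rejects missing or out-of-range inputs.
* All randomness flows from explicit integer seeds; identical seeds give
  byte-identical generator output and pipeline tables (verified by
  checksum in the tests).

## Known limitations

* The tree cut is a two-parameter simplification of the hybrid dynamic
  cut; highly nested module structure (modules inside modules) will merge
  or vanish depending on the dominant gap.
* The Pearson fallback for zero-MAD genes changes the estimator per gene,
  not per pair side; extremely sparse genes are better excluded upstream
  by variable-gene selection.
* Connectivity recomputation is quadratic in module size and linear in
  permutations; atlases beyond ~10⁴ cells × 10³ network genes call for
  blockwise strategies out of scope here.
* The enrichment score (marker `avg_logFC`, 0 elsewhere) ties non-markers;
  the rank test handles ties correctly, but collections whose sets are
  mostly non-markers have little power by design.
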