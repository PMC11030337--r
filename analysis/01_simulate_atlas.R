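#!/usr/bin/env Rscript

# Stage 1 — simulate the study-condition atlas and write it to disk.
#
# Conditions: 3,000 cells in 5 equal clusters, 1,000 genes, negative-binomial
# background (mean 0.6 counts/gene/cell, size 2), one high-specificity marker
# per cluster (90% detection in-cluster, 5% outside, 8-fold mean inflation),
# five disjoint 25-gene co-expression modules each driven by a latent factor
# active in a single cluster (sd 1, log-mean loading 2), 10 mitochondrial
# genes and 4% appended doublets.
#
# Writes: data/atlas/ (10x-style fixture + truth sidecars)

library(scmodnet)

seed <- as.integer(Sys.getenv("ATLAS_SEED", "1"))
design <- atlas_design(
  n_cells_per_cluster = rep(600, 5),
  n_genes = 1000,
  baseline_mean = 0.6,
  dispersion = 2,
  marker_plan = data.frame(gene = 126:130, cluster = 1:5,
                           in_fraction = 0.9, out_fraction = 0.05,
                           fold_change = 8),
  module_plan = lapply(1:5, function(m) {
    list(genes = ((m - 1) * 25 + 1):(m * 25), clusters = m,
         factor_sd = 1, loading = 2)
  }),
  mito_gene_indices = 991:1000,
  doublet_rate = 0.04,
  seed = seed
)
atlas <- generate_atlas(design)
write_fixture(atlas, "data/atlas")

message(sprintf("Simulated %d cells x %d genes (%d doublets appended) -> data/atlas/",
                nrow(atlas$counts), ncol(atlas$counts),
                sum(atlas$truth$is_doublet)))
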