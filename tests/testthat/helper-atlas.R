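# Study-condition synthetic atlas: 3,000 cells in 5 equal clusters, 1,000
# genes, 5 disjoint 25-gene co-expression modules each driven by one cluster
# (latent factor sd 1, log-mean loading 2), one high-specificity marker per
# cluster, 10 mitochondrial genes, 4% doublets. The same constructor backs
# the reproduction script.

study_design <- function(seed) {
  atlas_design(
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
}

## QC thresholds matched to the 1,000-gene desk-scale atlas (the count-based
## defaults target full-transcriptome data).
study_thresholds <- function() {
  qc_thresholds(min_features = 100, max_features = 950,
                max_total_counts = 1e5, max_pct_mito = 10,
                doublet_score_threshold = 0.5)
}

## Network stage of the pipeline on a generated atlas; returns the pieces
## downstream inference needs.
study_network <- function(atlas, n_variable = 300, power = 2,
                          min_module_size = 15) {
  filt <- filter_cells(atlas$metrics, study_thresholds())
  counts <- atlas$counts[filt$retained, ]
  labels <- atlas$labels[atlas$labels$cell_id %in% filt$retained, ]
  norm <- log_normalize(counts)
  vg <- select_variable_genes(norm, n_variable)
  X <- as.matrix(norm[, vg])
  cor <- bicor_matrix(X)
  tom <- tom_similarity(adjacency_matrix(cor, power))
  asg <- cut_modules(1 - tom, min_cluster_size = min_module_size)
  merged <- merge_modules(X, asg)
  list(filter = filt, labels = labels, norm = norm, variable_genes = vg,
       expr = X, assignment = merged$assignment,
       eigengenes = merged$eigengenes, power = power)
}

## ARI between recovered and planted module labels over the planted genes.
module_recovery_ari <- function(assignment, truth) {
  common <- intersect(truth$gene_id, names(assignment$module))
  ari(assignment$module[common], truth$module[match(common, truth$gene_id)])
}
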