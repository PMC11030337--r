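# Shared pipeline fixture: a written 10x-style synthetic atlas and a
# desk-scale configuration matched to its gene count.

pipeline_fixture <- function(dir, seed = 31) {
  design <- atlas_design(
    n_cells_per_cluster = rep(200, 4),
    n_genes = 300,
    baseline_mean = 0.6,
    marker_plan = data.frame(gene = 1:4, cluster = 1:4, in_fraction = 0.9,
                             out_fraction = 0.05, fold_change = 8),
    module_plan = list(
      list(genes = 11:35, clusters = c(1, 2), factor_sd = 1, loading = 2),
      list(genes = 36:60, clusters = c(3, 4), factor_sd = 1, loading = 2)
    ),
    mito_gene_indices = 291:300,
    doublet_rate = 0.04,
    seed = seed
  )
  write_fixture(generate_atlas(design), dir)
  dir
}

fixture_config <- function(fix, out, n_perm = 200, seed = 5L, gmt = NULL) {
  ## desk-scale thresholds for the 300-gene fixture
  pipeline_config(
    matrix_dir = fix, out_dir = out, gmt_path = gmt,
    min_features = 30, max_features = 295, max_total_counts = 1e5,
    max_pct_mito = 10, doublet_score_threshold = 0.5,
    n_variable = 100, min_module_size = 10,
    n_perm = n_perm, seed = seed
  )
}
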