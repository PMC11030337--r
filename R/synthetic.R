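# Seeded synthetic single-cell atlas generator: negative-binomial background,
# planted marker genes with exact in/out detection fractions, planted
# co-expression modules driven by cluster-restricted latent factors,
# mitochondrial-fraction structure and artificial doublets.

#' Describe a synthetic atlas design
#'
#' Collects and validates all parameters of a synthetic atlas: cluster sizes,
#' gene count, negative-binomial background, planted marker genes, planted
#' latent-factor co-expression modules, mitochondrial genes and doublet rate.
#'
#' @param n_cells_per_cluster integer vector, cells per cluster (one entry per
#'   cluster).
#' @param n_genes total number of genes.
#' @param baseline_mean expected background counts per gene per cell.
#' @param dispersion negative-binomial size parameter (inverse dispersion);
#'   smaller values give more overdispersion.
#' @param marker_plan `data.frame` with columns `gene` (index in
#'   `1..n_genes`), `cluster` (index in `1..n_clusters`), `in_fraction` in
#'   (0, 1], `out_fraction` in [0, 1) with `in_fraction > out_fraction`, and
#'   `fold_change` > 1 (in-cluster mean inflation). May be `NULL`.
#' @param module_plan list of module descriptions, each a list with fields
#'   `genes` (integer vector of gene indices), `clusters` (integer vector of
#'   active cluster indices), `factor_sd` > 0 and `loading` > 0. Module gene
#'   sets must be pairwise disjoint and must not overlap marker genes.
#' @param mito_gene_indices gene indices treated as mitochondrial.
#' @param doublet_rate fraction (of singlet cells) of extra doublet cells to
#'   append, in [0, 1).
#' @param seed integer seed; identical seeds give bit-identical atlases.
#' @return an object of class `atlas_design` (a validated list).
#' @export
atlas_design <- function(n_cells_per_cluster,
                         n_genes,
                         baseline_mean = 0.3,
                         dispersion = 2,
                         marker_plan = NULL,
                         module_plan = list(),
                         mito_gene_indices = integer(),
                         doublet_rate = 0,
                         seed = 1L) {
  .assert(length(n_cells_per_cluster) >= 1 && all(n_cells_per_cluster >= 1),
          "n_cells_per_cluster must be positive integers")
  .assert(n_genes >= 1, "n_genes must be positive")
  .assert(baseline_mean > 0, "baseline_mean must be positive")
  .assert(dispersion > 0, "dispersion must be positive")
  .assert(doublet_rate >= 0 && doublet_rate < 1, "doublet_rate must be in [0, 1)")
  n_clusters <- length(n_cells_per_cluster)
  if (!is.null(marker_plan)) {
    need <- c("gene", "cluster", "in_fraction", "out_fraction", "fold_change")
    .assert(all(need %in% names(marker_plan)),
            "marker_plan must have columns %s", paste(need, collapse = ", "))
    .assert(all(marker_plan$gene >= 1 & marker_plan$gene <= n_genes),
            "marker_plan gene indices out of range")
    .assert(all(marker_plan$cluster >= 1 & marker_plan$cluster <= n_clusters),
            "marker_plan cluster indices out of range")
    .assert(all(marker_plan$in_fraction > 0 & marker_plan$in_fraction <= 1),
            "in_fraction must be in (0, 1]")
    .assert(all(marker_plan$out_fraction >= 0 & marker_plan$out_fraction < 1),
            "out_fraction must be in [0, 1)")
    .assert(all(marker_plan$in_fraction > marker_plan$out_fraction),
            "in_fraction must exceed out_fraction for every marker")
    .assert(all(marker_plan$fold_change > 1, na.rm = TRUE),
            "fold_change must exceed 1")
    .assert(!anyDuplicated(marker_plan$gene),
            "a gene may appear only once in marker_plan")
  }
  module_genes <- integer()
  for (m in module_plan) {
    .assert(all(c("genes", "clusters", "factor_sd", "loading") %in% names(m)),
            "each module needs fields genes, clusters, factor_sd, loading")
    .assert(all(m$genes >= 1 & m$genes <= n_genes),
            "module gene indices out of range")
    .assert(all(m$clusters >= 1 & m$clusters <= n_clusters),
            "module cluster indices out of range")
    .assert(m$factor_sd > 0 && m$loading > 0,
            "factor_sd and loading must be positive")
    .assert(!any(m$genes %in% module_genes),
            "module gene sets must be pairwise disjoint")
    module_genes <- c(module_genes, m$genes)
  }
  if (!is.null(marker_plan) && length(module_genes)) {
    clash <- intersect(marker_plan$gene, module_genes)
    .assert(length(clash) == 0,
            "genes %s appear in both marker_plan and module_plan (conflicting cluster structure)",
            paste(clash, collapse = ", "))
  }
  .assert(all(mito_gene_indices >= 1 & mito_gene_indices <= n_genes),
          "mito_gene_indices out of range")
  structure(list(
    n_cells_per_cluster = as.integer(n_cells_per_cluster),
    n_genes = as.integer(n_genes),
    baseline_mean = baseline_mean,
    dispersion = dispersion,
    marker_plan = marker_plan,
    module_plan = module_plan,
    mito_gene_indices = as.integer(mito_gene_indices),
    doublet_rate = doublet_rate,
    seed = as.integer(seed)
  ), class = "atlas_design")
}

#' Generate a synthetic atlas from a design
#'
#' Draws a cells x genes count matrix with negative-binomial background.
#' Module genes share an additive latent factor on the log-mean: in cells of a
#' module's active clusters the per-cell factor is Normal(0, factor_sd) and
#' the gene mean is `baseline_mean * exp(loading * factor)`; elsewhere the
#' factor is zero. Marker genes are drawn as Bernoulli(detection fraction)
#' times `1 + NB`, so the planted in/out detection fractions are exact
#' Bernoulli rates (the in-cluster NB mean is inflated by `fold_change`).
#' Mitochondrial genes get a per-cell log-normal scale so that a realistic
#' minority of cells exceeds typical QC cutoffs. Doublets are appended as the
#' sums of two random parent cells' count vectors and flagged in the truth.
#'
#' @param design an [atlas_design()].
#' @return a list of class `synthetic_atlas` with elements `counts` (sparse
#'   cells x genes integer matrix), `metrics` (per-cell QC metrics including a
#'   doublet score), `labels` (`data.frame` of cell_id, cluster) and `truth`
#'   (cluster of cell, doublet flags, realized marker and module plans,
#'   per-cell latent factor values).
#' @export
generate_atlas <- function(design) {
  .assert(inherits(design, "atlas_design"), "design must be an atlas_design")
  set.seed(design$seed)
  n_clusters <- length(design$n_cells_per_cluster)
  n_base <- sum(design$n_cells_per_cluster)
  n_genes <- design$n_genes
  cluster_of_cell <- rep(seq_len(n_clusters), times = design$n_cells_per_cluster)

  log_mu <- matrix(log(design$baseline_mean), nrow = n_base, ncol = n_genes)

  factor_values <- NULL
  if (length(design$module_plan)) {
    factor_values <- matrix(0, nrow = n_base, ncol = length(design$module_plan))
    colnames(factor_values) <- paste0("module", seq_along(design$module_plan))
    for (mi in seq_along(design$module_plan)) {
      m <- design$module_plan[[mi]]
      active <- cluster_of_cell %in% m$clusters
      f <- numeric(n_base)
      f[active] <- stats::rnorm(sum(active), mean = 0, sd = m$factor_sd)
      factor_values[, mi] <- f
      log_mu[, m$genes] <- log_mu[, m$genes] + m$loading * f
    }
  }

  if (length(design$mito_gene_indices)) {
    ## per-cell mitochondrial load, median ~3% of library with a tail past 10%
    mito_scale <- stats::rlnorm(n_base, meanlog = log(3), sdlog = 0.8) *
      n_genes / max(1L, length(design$mito_gene_indices)) / 100
    log_mu[, design$mito_gene_indices] <-
      log_mu[, design$mito_gene_indices] + log(mito_scale)
  }

  counts <- matrix(
    stats::rnbinom(n_base * n_genes, mu = exp(as.vector(log_mu)),
                   size = design$dispersion),
    nrow = n_base, ncol = n_genes
  )

  if (!is.null(design$marker_plan)) {
    for (r in seq_len(nrow(design$marker_plan))) {
      mk <- design$marker_plan[r, ]
      g <- mk$gene
      inside <- cluster_of_cell == mk$cluster
      n_in <- sum(inside); n_out <- n_base - n_in
      counts[inside, g] <- stats::rbinom(n_in, 1L, mk$in_fraction) *
        (1L + stats::rnbinom(n_in, mu = design$baseline_mean * mk$fold_change,
                             size = design$dispersion))
      counts[!inside, g] <- stats::rbinom(n_out, 1L, mk$out_fraction) *
        (1L + stats::rnbinom(n_out, mu = design$baseline_mean,
                             size = design$dispersion))
    }
  }

  n_dbl <- floor(design$doublet_rate * n_base)
  is_doublet <- c(rep(FALSE, n_base), rep(TRUE, n_dbl))
  parents <- NULL
  if (n_dbl > 0) {
    parents <- cbind(sample.int(n_base, n_dbl, replace = TRUE),
                     sample.int(n_base, n_dbl, replace = TRUE))
    dbl <- counts[parents[, 1], , drop = FALSE] +
      counts[parents[, 2], , drop = FALSE]
    counts <- rbind(counts, dbl)
    cluster_of_cell <- c(cluster_of_cell, cluster_of_cell[parents[, 1]])
    if (!is.null(factor_values)) {
      factor_values <- rbind(factor_values,
                             factor_values[parents[, 1], , drop = FALSE])
    }
  }
  n_cells <- nrow(counts)

  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  dimnames(counts) <- list(cell_ids, gene_ids)

  doublet_score <- .doublet_scores(counts, is_doublet)
  mito_ids <- gene_ids[design$mito_gene_indices]
  metrics <- compute_metrics(counts, mito_gene_ids = mito_ids,
                             doublet_score = doublet_score)

  labels <- data.frame(cell_id = cell_ids,
                       cluster = cluster_of_cell,
                       stringsAsFactors = FALSE)

  module_truth <- data.frame(gene_id = character(), module = integer(),
                             stringsAsFactors = FALSE)
  if (length(design$module_plan)) {
    module_truth <- do.call(rbind, lapply(seq_along(design$module_plan),
      function(mi) data.frame(
        gene_id = gene_ids[design$module_plan[[mi]]$genes],
        module = mi, stringsAsFactors = FALSE)))
  }
  marker_truth <- design$marker_plan
  if (!is.null(marker_truth)) {
    marker_truth$gene_id <- gene_ids[marker_truth$gene]
  }

  truth <- list(
    cluster_of_cell = stats::setNames(cluster_of_cell, cell_ids),
    is_doublet = stats::setNames(is_doublet, cell_ids),
    marker_truth = marker_truth,
    module_truth = module_truth,
    factor_values = factor_values,
    doublet_parents = parents
  )

  structure(list(
    counts = Matrix::Matrix(counts, sparse = TRUE),
    metrics = metrics,
    labels = labels,
    truth = truth,
    design = design
  ), class = "synthetic_atlas")
}

## Continuous doublet score: similarity of each cell to the doublet
## population, measured on detected-gene complexity (doublets carry the union
## of two parents' genes) blended with cosine similarity to the mean doublet
## profile, rescaled to [0,1]. True doublets land near the top so a score
## threshold behaves like an external doublet caller's.
.doublet_scores <- function(counts, is_doublet) {
  n <- nrow(counts)
  if (!any(is_doublet)) return(numeric(n))
  profile <- colMeans(counts[is_doublet, , drop = FALSE])
  pn <- sqrt(sum(profile^2))
  norms <- sqrt(rowSums(counts^2))
  cosine <- as.vector(counts %*% profile) / (pmax(norms, 1e-12) * pn)
  complexity <- rowSums(counts > 0)
  complexity <- complexity / max(complexity)
  score <- 0.7 * complexity + 0.3 * cosine
  score <- (score - min(score)) / max(1e-12, diff(range(score)))
  unname(score)
}

#' Write a synthetic atlas to disk as a 10x-style fixture
#'
#' Emits `matrix.mtx` (Matrix Market coordinate integer, genes x rows as in
#' the 10x convention), `genes.tsv`, `barcodes.tsv`, `labels.tsv`,
#' `metrics.tsv` and truth sidecars (`truth_cells.tsv`, `truth_markers.tsv`,
#' `truth_modules.tsv`). Files round-trip losslessly through
#' [read_counts_mtx()].
#'
#' @param atlas a `synthetic_atlas` from [generate_atlas()].
#' @param directory output directory, created if missing.
#' @return the directory, invisibly.
#' @export
write_fixture <- function(atlas, directory) {
  .assert(inherits(atlas, "synthetic_atlas"), "atlas must be a synthetic_atlas")
  if (!dir.exists(directory)) {
    ok <- dir.create(directory, recursive = TRUE, showWarnings = FALSE)
    .assert(ok, "cannot create directory '%s'", directory)
  }
  counts <- atlas$counts
  ## 10x on-disk convention is genes x cells
  .write_mtx_integer(Matrix::t(counts), file.path(directory, "matrix.mtx"))
  gene_ids <- colnames(counts)
  utils::write.table(data.frame(gene_ids, gene_ids),
                     file.path(directory, "genes.tsv"),
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  writeLines(rownames(counts), file.path(directory, "barcodes.tsv"))
  utils::write.table(atlas$labels, file.path(directory, "labels.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(atlas$metrics, file.path(directory, "metrics.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  truth_cells <- data.frame(
    cell_id = rownames(counts),
    cluster = unname(atlas$truth$cluster_of_cell),
    is_doublet = unname(atlas$truth$is_doublet),
    stringsAsFactors = FALSE
  )
  utils::write.table(truth_cells, file.path(directory, "truth_cells.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(atlas$truth$marker_truth)) {
    utils::write.table(atlas$truth$marker_truth,
                       file.path(directory, "truth_markers.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(atlas$truth$module_truth,
                     file.path(directory, "truth_modules.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(directory)
}

## Matrix Market coordinate writer with the integer field declared (the
## standard writer declares 'real' for numeric sparse matrices).
.write_mtx_integer <- function(m, path) {
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  tr <- Matrix::summary(m)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(tr))), con)
  if (nrow(tr)) {
    writeLines(sprintf("%d %d %d", tr$i, tr$j, as.integer(tr$x)), con)
  }
  invisible(path)
}
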