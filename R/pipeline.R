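# End-to-end pipeline driver: QC filter -> normalize -> variable genes ->
# markers -> enrichment -> network -> module-cluster statistics, writing
# every intermediate table and a reproducibility manifest.

#' Pipeline configuration
#'
#' Bundles input paths and every stage parameter with its default:
#' QC thresholds (min 500 / max 9000 features, 1e5 counts, 10% mito),
#' log-fold-change cutoff 0.25, specificity fractions 0.60 / 0.10,
#' 3000 variable genes, bicor `max_p_outliers` 0.05, soft power override 2,
#' minimum module size 15, deep split 2, merge cutoff 0.35, 1000
#' permutations, alpha 0.05. Parameters are validated here; `n_variable` is
#' re-validated against the matrix at run time.
#'
#' @param matrix_dir directory with `matrix.mtx`, `genes.tsv`,
#'   `barcodes.tsv`, `metrics.tsv`, `labels.tsv` (as written by
#'   [write_fixture()]).
#' @param out_dir output directory for result tables.
#' @param gmt_path optional GMT gene-set file; enrichment is skipped when
#'   `NULL`.
#' @param min_features,max_features,max_total_counts,max_pct_mito,doublet_score_threshold
#'   QC thresholds, see [qc_thresholds()].
#' @param scale_total library-size normalization target.
#' @param logfc_threshold rank-sum marker log-fold-change cutoff.
#' @param in_min,out_max specificity-rule detection fractions.
#' @param n_variable number of variable genes for the network.
#' @param max_p_outliers bicor per-side outlier cap.
#' @param power soft-threshold power override (`NULL` to select from fit).
#' @param min_module_size,deep_split,merge_cutoff module detection settings.
#' @param n_perm permutations for both inference procedures.
#' @param alpha nominal FDR level recorded in the manifest.
#' @param seed master seed; stage seeds are derived from it.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(matrix_dir, out_dir, gmt_path = NULL,
                            min_features = 500, max_features = 9000,
                            max_total_counts = 1e5, max_pct_mito = 10,
                            doublet_score_threshold = 1,
                            scale_total = 1e4,
                            logfc_threshold = 0.25,
                            in_min = 0.60, out_max = 0.10,
                            n_variable = 3000,
                            max_p_outliers = 0.05,
                            power = 2,
                            min_module_size = 15, deep_split = 2,
                            merge_cutoff = 0.35,
                            n_perm = 1000, alpha = 0.05, seed = 1L) {
  thresholds <- qc_thresholds(min_features, max_features, max_total_counts,
                              max_pct_mito, doublet_score_threshold)
  .assert(n_variable >= 2, "n_variable must be at least 2")
  .assert(in_min > out_max, "in_min must exceed out_max")
  .assert(n_perm >= 100, "n_perm must be at least 100")
  .assert(alpha > 0 && alpha < 1, "alpha must be in (0, 1)")
  structure(list(
    matrix_dir = matrix_dir, out_dir = out_dir, gmt_path = gmt_path,
    thresholds = thresholds, scale_total = scale_total,
    logfc_threshold = logfc_threshold, in_min = in_min, out_max = out_max,
    n_variable = n_variable, max_p_outliers = max_p_outliers, power = power,
    min_module_size = min_module_size, deep_split = deep_split,
    merge_cutoff = merge_cutoff, n_perm = n_perm, alpha = alpha,
    seed = as.integer(seed)
  ), class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes, in order: QC filtering, log normalization, variable-gene
#' selection, rank-sum and specificity marker detection, best-marker
#' selection, optional gene-set enrichment of each cluster's markers,
#' co-expression network construction (bicor, soft threshold, TOM, module
#' detection, eigengenes, merging), permutation association of modules with
#' clusters, and leave-cluster-out connectivity analysis. Every intermediate
#' table is written under `config$out_dir` along with `manifest.json`
#' (package version, parameters, seed, input/output checksums). Outputs are a
#' pure function of (inputs, config); a rerun with the same seed is
#' byte-identical. On a stage failure, tables already written are renamed
#' with a `.partial` suffix and the error names the stage.
#'
#' @param config a [pipeline_config()].
#' @return invisible list with all in-memory results (`metrics`, `filter`,
#'   `norm`, `variable_genes`, `markers_ranksum`, `markers_specificity`,
#'   `best_markers`, `enrichment`, `network`, `association`, `connectivity`,
#'   `manifest`).
#' @export
run_pipeline <- function(config) {
  .assert(inherits(config, "pipeline_config"),
          "config must come from pipeline_config()")
  out <- config$out_dir
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  written <- character()
  stage <- "setup"
  emit <- function(tab, name, tsv = FALSE) {
    path <- file.path(out, name)
    if (tsv) .write_tsv(tab, path) else .write_csv(tab, path)
    written <<- c(written, path)
    path
  }
  result <- tryCatch({
    stage <- "read_inputs"
    counts <- read_counts_mtx(config$matrix_dir)
    metrics <- read_metrics(file.path(config$matrix_dir, "metrics.tsv"))
    labels <- read_labels(file.path(config$matrix_dir, "labels.tsv"))
    .assert(config$n_variable <= ncol(counts),
            "n_variable (%d) exceeds the number of genes (%d)",
            config$n_variable, ncol(counts))
    input_files <- file.path(config$matrix_dir,
                             c("matrix.mtx", "genes.tsv", "barcodes.tsv",
                               "metrics.tsv", "labels.tsv"))

    stage <- "qc_filter"
    filt <- filter_cells(metrics, config$thresholds)
    emit(filt$table, "qc_cells.tsv", tsv = TRUE)
    counts <- counts[filt$retained, , drop = FALSE]
    labels <- labels[labels$cell_id %in% filt$retained, , drop = FALSE]

    stage <- "normalize"
    norm <- log_normalize(counts, scale_total = config$scale_total)

    stage <- "variable_genes"
    vg <- select_variable_genes(norm, config$n_variable)
    emit(data.frame(gene = vg), "variable_genes.tsv", tsv = TRUE)

    stage <- "markers"
    mk_rs <- ranksum_markers(norm, labels,
                             logfc_threshold = config$logfc_threshold)
    mk_sp <- specificity_markers(counts, labels,
                                 in_min = config$in_min,
                                 out_max = config$out_max)
    best <- best_marker_per_cluster(
      list(mk_sp, mk_rs),
      clusters = sort(unique(as.character(labels$cluster))))
    emit(mk_rs, "markers_ranksum.csv")
    emit(mk_sp, "markers_specificity.csv")
    emit(best, "best_markers.csv")

    stage <- "enrichment"
    enrichment <- NULL
    if (!is.null(config$gmt_path)) {
      sets <- read_gmt(config$gmt_path)
      universe <- colnames(counts)
      enrichment <- do.call(rbind, lapply(
        sort(unique(as.character(labels$cluster))), function(cl) {
          scores <- marker_scores(mk_rs, cl, universe)
          tab <- wilcoxon_enrichment(scores, sets, universe)
          if (nrow(tab)) cbind(cluster = cl, tab) else NULL
        }))
      if (!is.null(enrichment)) emit(enrichment, "enrichment.csv")
    }

    stage <- "network"
    Xnet <- as.matrix(norm[, vg, drop = FALSE])
    cor <- bicor_matrix(Xnet, max_p_outliers = config$max_p_outliers)
    st <- pick_soft_threshold(cor, override = config$power)
    emit(st$fit_table, "soft_threshold.csv")
    adj <- adjacency_matrix(cor, st$power)
    tom <- tom_similarity(adj)
    assignment <- cut_modules(1 - tom,
                              min_cluster_size = config$min_module_size,
                              deep_split = config$deep_split)
    merged <- merge_modules(Xnet, assignment,
                            dissim_cutoff = config$merge_cutoff)
    emit(data.frame(gene = names(merged$assignment$module),
                    module = unname(merged$assignment$module)),
         "modules.tsv", tsv = TRUE)
    eig <- merged$eigengenes
    emit(data.frame(cell_id = rownames(eig), as.data.frame(eig),
                    check.names = FALSE),
         "eigengenes.csv")

    stage <- "association"
    assoc <- permutation_association(eig, labels, n_perm = config$n_perm,
                                     seed = config$seed + 1L)
    emit(assoc, "association.csv")

    stage <- "connectivity"
    conn <- connectivity_drop(Xnet, merged$assignment, labels,
                              beta = st$power, n_perm = config$n_perm,
                              seed = config$seed + 2L)
    emit(conn, "connectivity.csv")

    stage <- "manifest"
    manifest <- list(
      package = "scmodnet",
      version = as.character(utils::packageVersion("scmodnet")),
      seed = config$seed,
      parameters = unclass(config)[setdiff(names(unclass(config)),
                                           c("matrix_dir", "out_dir",
                                             "gmt_path"))],
      input_checksums = as.list(stats::setNames(tools::md5sum(input_files),
                                                basename(input_files))),
      output_checksums = as.list(stats::setNames(tools::md5sum(sort(written)),
                                                 basename(sort(written))))
    )
    manifest$parameters$thresholds <- unclass(manifest$parameters$thresholds)
    manifest_path <- file.path(out, "manifest.json")
    jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)

    list(metrics = metrics, filter = filt, norm = norm, variable_genes = vg,
         markers_ranksum = mk_rs, markers_specificity = mk_sp,
         best_markers = best, enrichment = enrichment,
         network = list(correlation = cor, power = st$power,
                        fit_table = st$fit_table, tom = tom,
                        assignment = merged$assignment,
                        eigengenes = eig,
                        var_explained = merged$var_explained),
         association = assoc, connectivity = conn, manifest = manifest)
  }, error = function(e) {
    for (p in written) {
      if (file.exists(p)) file.rename(p, paste0(p, ".partial"))
    }
    stop(sprintf("pipeline failed at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
  invisible(result)
}
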