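# Cell-level quality control: per-cell metrics, threshold filtering with
# exclusion reasons, log library-size normalization, variable-gene selection.

#' Compute per-cell QC metrics
#'
#' @param counts cells x genes count matrix (dense or sparse) with cell and
#'   gene identifiers as dimnames.
#' @param mito_gene_ids identifiers of mitochondrial genes; must all be
#'   present among the matrix's gene identifiers.
#' @param doublet_score optional per-cell doublet score in `[0, 1]`; defaults
#'   to 0 for every cell.
#' @return `data.frame` with columns `cell_id`, `n_features`, `total_counts`,
#'   `pct_mito` (percentage in `[0, 100]`; 0 for zero-total cells, which are
#'   flagged in `zero_total`) and `doublet_score`.
#' @export
compute_metrics <- function(counts, mito_gene_ids = character(),
                            doublet_score = NULL) {
  m <- .as_dense(counts)
  .assert(!is.null(rownames(m)) && !is.null(colnames(m)),
          "counts must carry cell and gene identifiers as dimnames")
  unknown <- setdiff(mito_gene_ids, colnames(m))
  .assert(length(unknown) == 0, "unknown mitochondrial gene id(s): %s",
          paste(unknown, collapse = ", "))
  n_features <- rowSums(m > 0)
  total <- rowSums(m)
  mito_total <- if (length(mito_gene_ids)) {
    rowSums(m[, mito_gene_ids, drop = FALSE])
  } else {
    numeric(nrow(m))
  }
  pct_mito <- ifelse(total > 0, 100 * mito_total / total, 0)
  if (is.null(doublet_score)) doublet_score <- numeric(nrow(m))
  .assert(length(doublet_score) == nrow(m),
          "doublet_score must have one value per cell")
  data.frame(
    cell_id = rownames(m),
    n_features = as.integer(n_features),
    total_counts = as.integer(round(total)),
    pct_mito = unname(pct_mito),
    doublet_score = unname(doublet_score),
    zero_total = total == 0,
    stringsAsFactors = FALSE
  )
}

#' QC filtering thresholds
#'
#' Bundles the cell-retention thresholds. Removal criteria are strict
#' inequalities ("less than 500 features", "greater than 9000 features",
#' "greater than 1e5 counts", "greater than 10% mitochondrial", score greater
#' than the doublet threshold), so cells sitting exactly on a threshold are
#' retained.
#'
#' @param min_features,max_features feature-count bounds (defaults 500, 9000).
#' @param max_total_counts total-count ceiling (default 1e5).
#' @param max_pct_mito mitochondrial percentage ceiling (default 10).
#' @param doublet_score_threshold per-sample doublet score ceiling; no
#'   universal default, must be supplied explicitly.
#' @return an object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_features = 500, max_features = 9000,
                          max_total_counts = 1e5, max_pct_mito = 10,
                          doublet_score_threshold = 1) {
  .assert(min_features < max_features, "min_features must be < max_features")
  .assert(min_features > 0 && max_total_counts > 0 && max_pct_mito > 0 &&
            doublet_score_threshold > 0, "all thresholds must be positive")
  structure(list(min_features = min_features, max_features = max_features,
                 max_total_counts = max_total_counts,
                 max_pct_mito = max_pct_mito,
                 doublet_score_threshold = doublet_score_threshold),
            class = "qc_thresholds")
}

#' Filter cells on QC metrics
#'
#' A cell is retained iff `n_features >= min_features`,
#' `n_features <= max_features`, `total_counts <= max_total_counts`,
#' `doublet_score <= doublet_score_threshold` and
#' `pct_mito <= max_pct_mito`. Every excluded cell carries all reason codes
#' that apply (`min_features`, `max_features`, `max_counts`, `doublet`,
#' `mito`).
#'
#' @param metrics `data.frame` as from [compute_metrics()] (must include a
#'   `doublet_score` column).
#' @param thresholds a [qc_thresholds()] object.
#' @return list with `retained` (character vector of retained cell ids) and
#'   `table` (`data.frame` of cell_id, retained flag, comma-joined reasons).
#' @export
filter_cells <- function(metrics, thresholds) {
  .assert(inherits(thresholds, "qc_thresholds"),
          "thresholds must come from qc_thresholds()")
  need <- c("cell_id", "n_features", "total_counts", "pct_mito", "doublet_score")
  .assert(all(need %in% names(metrics)),
          "metrics must have columns %s", paste(need, collapse = ", "))
  bad <- metrics$cell_id[!stats::complete.cases(metrics[, need])]
  .assert(length(bad) == 0, "missing metric value(s) for cell(s): %s",
          paste(bad, collapse = ", "))
  reasons <- cbind(
    min_features = metrics$n_features < thresholds$min_features,
    max_features = metrics$n_features > thresholds$max_features,
    max_counts = metrics$total_counts > thresholds$max_total_counts,
    doublet = metrics$doublet_score > thresholds$doublet_score_threshold,
    mito = metrics$pct_mito > thresholds$max_pct_mito
  )
  retained <- rowSums(reasons) == 0
  reason_str <- apply(reasons, 1L, function(r) {
    paste(colnames(reasons)[r], collapse = ",")
  })
  tab <- data.frame(cell_id = metrics$cell_id,
                    retained = retained,
                    reasons = reason_str,
                    stringsAsFactors = FALSE)
  list(retained = metrics$cell_id[retained], table = tab)
}

#' Log library-size normalization
#'
#' `value = log(1 + count * scale_total / cell_total)` (natural log).
#' Zero counts map to zero, so sparsity is preserved; zero-total cells give
#' all-zero rows and a warning.
#'
#' @param counts cells x genes non-negative integer matrix (dense or sparse).
#' @param scale_total target library size (default 1e4).
#' @return sparse cells x genes matrix of normalized expression.
#' @export
log_normalize <- function(counts, scale_total = 1e4) {
  .assert(scale_total > 0, "scale_total must be positive")
  m <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                               "CsparseMatrix"), "generalMatrix")
  .assert(all(m@x >= 0), "counts must be non-negative")
  .assert(all(abs(m@x - round(m@x)) < 1e-8), "counts must be integers")
  totals <- Matrix::rowSums(m)
  .assert(any(totals > 0), "at least one cell must have nonzero total")
  if (any(totals == 0)) {
    warning(sprintf("%d cell(s) have zero total counts; their rows are all zero",
                    sum(totals == 0)))
  }
  tr <- Matrix::summary(m)
  denom <- totals[tr$i]
  x <- ifelse(denom > 0, log1p(tr$x * scale_total / denom), 0)
  out <- Matrix::sparseMatrix(i = tr$i, j = tr$j, x = x,
                              dims = dim(m), dimnames = dimnames(m))
  out
}

#' Select highly variable genes
#'
#' Ranks genes by dispersion of normalized expression, defined as
#' variance / mean of the normalized values, and returns the top `n` gene
#' ids. Genes never expressed rank last; ties are broken by gene order, so
#' the result is deterministic and independent of cell order.
#'
#' @param norm normalized cells x genes matrix (dense or sparse).
#' @param n number of genes to select (`1 <= n <= n_genes`).
#' @return character vector of `n` gene ids, ordered by decreasing dispersion.
#' @export
select_variable_genes <- function(norm, n) {
  .assert(n >= 1, "n must be positive")
  .assert(n <= ncol(norm), "n exceeds the number of genes")
  m <- .as_dense(norm)
  mu <- colMeans(m)
  v <- colMeans(m^2) - mu^2
  v <- v * nrow(m) / max(1, nrow(m) - 1)
  disp <- ifelse(mu > 0, v / mu, -Inf)
  ord <- order(-disp, seq_along(disp))
  colnames(m)[ord[seq_len(n)]]
}
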