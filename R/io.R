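# Readers for the on-disk formats: Matrix Market counts with 10x sidecars,
# metrics and label tables.

#' Read a Matrix Market count matrix with 10x sidecars
#'
#' Reads `matrix.mtx`, `genes.tsv` (first column = gene id) and
#' `barcodes.tsv` from a directory (or explicit paths). Orientation is
#' auto-detected from sidecar lengths: the 10x convention stores genes x
#' cells, which is transposed so cells index rows. Duplicate gene ids are
#' disambiguated deterministically with numeric suffixes and a warning.
#'
#' @param directory directory containing the triplet files.
#' @param matrix_path,genes_path,barcodes_path explicit paths overriding the
#'   directory convention.
#' @return sparse cells x genes integer count matrix with cell/gene dimnames.
#' @export
read_counts_mtx <- function(directory = NULL,
                            matrix_path = NULL, genes_path = NULL,
                            barcodes_path = NULL) {
  if (!is.null(directory)) {
    matrix_path <- matrix_path %||% file.path(directory, "matrix.mtx")
    genes_path <- genes_path %||% file.path(directory, "genes.tsv")
    barcodes_path <- barcodes_path %||% file.path(directory, "barcodes.tsv")
  }
  for (p in c(matrix_path, genes_path, barcodes_path)) {
    .assert(!is.null(p) && file.exists(p), "input file not found: %s",
            p %||% "(unspecified)")
  }
  m <- Matrix::readMM(matrix_path)
  header <- readLines(matrix_path, n = 1)
  if (grepl("integer", header, fixed = TRUE) || grepl("real", header, fixed = TRUE)) {
    .assert(all(abs(m@x - round(m@x)) < 1e-8),
            "non-integer values in count matrix %s", matrix_path)
  }
  genes <- utils::read.table(genes_path, sep = "\t", header = FALSE,
                             stringsAsFactors = FALSE)[[1]]
  barcodes <- readLines(barcodes_path)
  if (nrow(m) == length(genes) && ncol(m) == length(barcodes)) {
    m <- Matrix::t(m)                       # 10x orientation: genes x cells
  } else {
    .assert(nrow(m) == length(barcodes) && ncol(m) == length(genes),
            "matrix dimensions %dx%d match neither sidecar orientation (%d genes, %d barcodes)",
            nrow(m), ncol(m), length(genes), length(barcodes))
  }
  if (anyDuplicated(genes)) {
    warning("duplicate gene ids disambiguated with numeric suffixes")
    genes <- make.unique(genes, sep = "-")
  }
  m <- methods::as(methods::as(m, "CsparseMatrix"), "generalMatrix")
  dimnames(m) <- list(barcodes, genes)
  m
}

#' Read a per-cell metrics table
#'
#' TSV with columns `cell_id`, `n_features`, `total_counts`, `pct_mito`,
#' `doublet_score`.
#'
#' @param path path to the TSV file.
#' @return `data.frame` of metrics.
#' @export
read_metrics <- function(path) {
  .assert(file.exists(path), "metrics file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  need <- c("cell_id", "n_features", "total_counts", "pct_mito", "doublet_score")
  .assert(all(need %in% names(tab)), "metrics file %s must have columns %s",
          path, paste(need, collapse = ", "))
  tab
}

#' Read per-cell cluster labels
#'
#' TSV with columns `cell_id`, `cluster`.
#'
#' @param path path to the TSV file.
#' @return `data.frame` with `cell_id` and `cluster`.
#' @export
read_labels <- function(path) {
  .assert(file.exists(path), "labels file not found: %s", path)
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  .assert(all(c("cell_id", "cluster") %in% names(tab)),
          "labels file %s must have columns cell_id, cluster", path)
  tab
}

## CSV writer with fixed conventions: "." decimal, no quoting of numbers,
## NA as empty field.
.write_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

.write_tsv <- function(tab, path) {
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
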