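# Dual cluster-marker detection: Wilcoxon rank-sum markers with a positive
# log-fold-change cutoff, and the strict 60%-in / 10%-out detection-fraction
# specificity rule; plus best-marker selection and targeted gene queries.

.check_labels <- function(labels, ids, min_cells = 2L) {
  if (is.data.frame(labels)) {
    .assert(all(c("cell_id", "cluster") %in% names(labels)),
            "labels data.frame needs columns cell_id, cluster")
    lab <- stats::setNames(as.character(labels$cluster), labels$cell_id)
    lab <- lab[ids]
  } else {
    lab <- as.character(labels)
    if (!is.null(names(lab))) lab <- lab[ids]
  }
  .assert(!anyNA(lab) && length(lab) == length(ids),
          "every cell must carry a cluster label")
  sizes <- table(lab)
  small <- names(sizes)[sizes < min_cells]
  .assert(length(small) == 0, "cluster(s) with fewer than %d cells: %s",
          min_cells, paste(small, collapse = ", "))
  lab
}

#' Wilcoxon rank-sum cluster markers
#'
#' For each cluster, each gene's normalized expression is compared between
#' in-cluster cells and all other cells with a two-sided Wilcoxon rank-sum
#' test (normal approximation with tie correction; exact enumeration for
#' fewer than 10 cells). Only genes whose average log fold change passes
#' `logfc_threshold` (and is positive when `positive_only`) are reported.
#' `avg_logFC = log(mean(expm1(in)) + 1) - log(mean(expm1(out)) + 1)`
#' (natural log, pseudocount 1). BH correction is applied jointly across all
#' reported (gene, cluster) records.
#'
#' @param norm normalized cells x genes matrix.
#' @param labels per-cell cluster labels (vector or `data.frame` with
#'   `cell_id`, `cluster`); every cluster needs at least 2 cells.
#' @param logfc_threshold minimum average log fold change (default 0.25).
#' @param positive_only keep only up-regulated markers (default `TRUE`).
#' @return `data.frame` with columns `gene`, `cluster`, `avg_logFC`,
#'   `p_value`, `q_value`, `pct_in`, `pct_out_max`.
#' @export
ranksum_markers <- function(norm, labels, logfc_threshold = 0.25,
                            positive_only = TRUE) {
  X <- .as_dense(norm)
  lab <- .check_labels(labels, rownames(X))
  clusters <- sort(unique(lab))
  .assert(length(clusters) >= 2, "need at least 2 clusters")
  rt <- .ranks_and_ties(X)
  frac <- .detection_fractions(X, lab)
  expm <- expm1(X)
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    inside <- which(lab == cl)
    test <- .ranksum_test(X, inside, "two.sided", rt = rt)
    mean_in <- colMeans(expm[inside, , drop = FALSE])
    mean_out <- colMeans(expm[-inside, , drop = FALSE])
    lfc <- log(mean_in + 1) - log(mean_out + 1)
    keep <- lfc >= logfc_threshold
    if (positive_only) keep <- keep & lfc > 0
    if (!any(keep)) next
    others <- setdiff(rownames(frac), cl)
    pct_out_max <- apply(frac[others, keep, drop = FALSE], 2L, max)
    out[[ci]] <- data.frame(
      gene = colnames(X)[keep],
      cluster = cl,
      avg_logFC = unname(lfc[keep]),
      p_value = test$p_value[keep],
      pct_in = unname(frac[cl, keep]),
      pct_out_max = unname(pct_out_max),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    return(data.frame(gene = character(), cluster = character(),
                      avg_logFC = numeric(), p_value = numeric(),
                      q_value = numeric(), pct_in = numeric(),
                      pct_out_max = numeric(), stringsAsFactors = FALSE))
  }
  res$q_value <- fdr_correct(res$p_value)
  res <- res[order(res$cluster, res$p_value, -res$avg_logFC, res$gene), ]
  rownames(res) <- NULL
  res[, c("gene", "cluster", "avg_logFC", "p_value", "q_value",
          "pct_in", "pct_out_max")]
}

#' Specificity markers by detection fraction
#'
#' A gene marks a cluster iff it is detected (raw count > 0) in strictly more
#' than `in_min` of the cluster's cells and in strictly less than `out_max`
#' of the cells of every other cluster. With `in_min >= out_max` a gene can
#' mark at most one cluster. Depends only on the zero/nonzero pattern of the
#' counts.
#'
#' @param counts cells x genes count matrix.
#' @param labels per-cell cluster labels.
#' @param in_min in-cluster detection fraction that must be exceeded
#'   (default 0.60).
#' @param out_max out-cluster detection fraction bound (default 0.10).
#' @return `data.frame` with columns `gene`, `cluster`, `pct_in`,
#'   `pct_out_max`.
#' @export
specificity_markers <- function(counts, labels, in_min = 0.60, out_max = 0.10) {
  .assert(in_min >= 0 && in_min <= 1 && out_max >= 0 && out_max <= 1,
          "fractions must be in [0, 1]")
  .assert(in_min > out_max, "in_min must exceed out_max")
  m <- .as_dense(counts)
  lab <- .check_labels(labels, rownames(m), min_cells = 1L)
  frac <- .detection_fractions(m, lab)
  clusters <- rownames(frac)
  .assert(length(clusters) >= 2, "need at least 2 clusters")
  out <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    cl <- clusters[ci]
    others <- setdiff(clusters, cl)
    pom <- apply(frac[others, , drop = FALSE], 2L, max)
    hit <- frac[cl, ] > in_min & pom < out_max
    if (!any(hit)) next
    out[[ci]] <- data.frame(
      gene = colnames(m)[hit],
      cluster = cl,
      pct_in = unname(frac[cl, hit]),
      pct_out_max = unname(pom[hit]),
      stringsAsFactors = FALSE
    )
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(gene = character(), cluster = character(),
                      pct_in = numeric(), pct_out_max = numeric(),
                      stringsAsFactors = FALSE)
  }
  rownames(res) <- NULL
  res
}

#' Best single marker per cluster
#'
#' From pooled candidate records (specificity and/or rank-sum markers,
#' which both carry `pct_in` and `pct_out_max`), selects per cluster the
#' candidate maximizing the margin `pct_in - pct_out_max`; ties broken by
#' larger `pct_in`, then lexicographically smaller gene id. Clusters without
#' candidates are listed with `NA`.
#'
#' @param records a `data.frame` (or list of data.frames, rbound) with
#'   columns `gene`, `cluster`, `pct_in`, `pct_out_max`.
#' @param clusters optional full set of cluster ids so unmarked clusters are
#'   reported too.
#' @return `data.frame` with one row per cluster: `cluster`, `gene`,
#'   `pct_in`, `pct_out_max`, `margin`.
#' @export
best_marker_per_cluster <- function(records, clusters = NULL) {
  if (is.list(records) && !is.data.frame(records)) {
    records <- do.call(rbind, lapply(records, function(r) {
      r[, c("gene", "cluster", "pct_in", "pct_out_max")]
    }))
  }
  need <- c("gene", "cluster", "pct_in", "pct_out_max")
  .assert(all(need %in% names(records)),
          "records must have columns %s", paste(need, collapse = ", "))
  records <- unique(records[, need])
  if (is.null(clusters)) clusters <- sort(unique(records$cluster))
  rows <- lapply(clusters, function(cl) {
    cand <- records[records$cluster == cl, , drop = FALSE]
    if (nrow(cand) == 0) {
      return(data.frame(cluster = cl, gene = NA_character_,
                        pct_in = NA_real_, pct_out_max = NA_real_,
                        margin = NA_real_, stringsAsFactors = FALSE))
    }
    margin <- cand$pct_in - cand$pct_out_max
    ord <- order(-margin, -cand$pct_in, cand$gene)
    best <- cand[ord[1], ]
    data.frame(cluster = cl, gene = best$gene, pct_in = best$pct_in,
               pct_out_max = best$pct_out_max,
               margin = best$pct_in - best$pct_out_max,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Per-cluster detection fractions for queried genes
#'
#' Reports each queried gene's detection fraction in every cluster and
#' whether it satisfies the specificity rule (strictly more than `in_min`
#' detected in the target cluster, strictly less than `out_max` in every
#' other cluster) — a generalized cell-type-restricted gene census.
#'
#' @param counts cells x genes count matrix.
#' @param labels per-cell cluster labels.
#' @param gene_ids genes to query (must exist).
#' @param target_cluster cluster against which restriction is evaluated.
#' @inheritParams specificity_markers
#' @return list with `fractions` (genes x clusters matrix) and `table`
#'   (`data.frame` of gene, pct_in_target, pct_out_max, restricted flag).
#' @export
celltype_restricted_genes <- function(counts, labels, gene_ids, target_cluster,
                                      in_min = 0.60, out_max = 0.10) {
  m <- .as_dense(counts)
  unknown <- setdiff(gene_ids, colnames(m))
  .assert(length(unknown) == 0, "unknown gene id(s): %s",
          paste(unknown, collapse = ", "))
  if (length(gene_ids) == 0) {
    return(list(fractions = matrix(numeric(), nrow = 0, ncol = 0),
                table = data.frame(gene = character(),
                                   pct_in_target = numeric(),
                                   pct_out_max = numeric(),
                                   restricted = logical(),
                                   stringsAsFactors = FALSE)))
  }
  lab <- .check_labels(labels, rownames(m), min_cells = 1L)
  .assert(as.character(target_cluster) %in% lab,
          "unknown target cluster '%s'", target_cluster)
  frac <- .detection_fractions(m[, gene_ids, drop = FALSE], lab)
  target <- as.character(target_cluster)
  others <- setdiff(rownames(frac), target)
  pin <- frac[target, ]
  pom <- if (length(others)) {
    apply(frac[others, , drop = FALSE], 2L, max)
  } else {
    stats::setNames(numeric(ncol(frac)), colnames(frac))
  }
  tab <- data.frame(gene = gene_ids,
                    pct_in_target = unname(pin[gene_ids]),
                    pct_out_max = unname(pom[gene_ids]),
                    restricted = unname(pin[gene_ids] > in_min &
                                          pom[gene_ids] < out_max),
                    stringsAsFactors = FALSE)
  list(fractions = t(frac), table = tab)
}
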