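# Gene-set enrichment of cluster markers: GMT parsing, one-sided Wilcoxon
# rank-sum enrichment of marker scores, and module-pathway membership counts
# with a minimum-overlap reporting rule.

#' Read a GMT gene-set collection
#'
#' Each line is `set_name <tab> description <tab> member1 <tab> member2 ...`.
#' Duplicate members within a set are dropped with a warning; a set with no
#' members is rejected.
#'
#' @param path path to the GMT file.
#' @return named list of character vectors (class `geneset_collection`),
#'   with per-set descriptions in the `descriptions` attribute.
#' @export
read_gmt <- function(path) {
  .assert(file.exists(path), "GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  descs <- character()
  for (k in seq_along(lines)) {
    fields <- strsplit(lines[[k]], "\t", fixed = TRUE)[[1]]
    .assert(length(fields) >= 3,
            "malformed GMT line %d: need name, description and >= 1 member", k)
    name <- fields[1]
    members <- fields[-(1:2)]
    members <- members[nzchar(members)]
    .assert(length(members) >= 1, "malformed GMT line %d: empty member list", k)
    if (anyDuplicated(members)) {
      warning(sprintf("duplicate gene(s) in set '%s' (line %d) deduplicated",
                      name, k))
      members <- unique(members)
    }
    .assert(!name %in% names(sets), "duplicate set name '%s' (line %d)", name, k)
    sets[[name]] <- members
    descs[name] <- fields[2]
  }
  structure(sets, descriptions = descs, class = "geneset_collection")
}

#' Score table for enrichment from a cluster's marker records
#'
#' Maps every gene of the universe to its marker `avg_logFC` for one cluster,
#' with 0 for genes not reported as markers of that cluster.
#'
#' @param markers marker `data.frame` as from [ranksum_markers()].
#' @param cluster cluster whose markers provide the scores.
#' @param universe character vector of all genes tested.
#' @return named numeric vector over `universe`.
#' @export
marker_scores <- function(markers, cluster, universe) {
  scores <- stats::setNames(numeric(length(universe)), universe)
  hit <- markers[markers$cluster == as.character(cluster) &
                   markers$gene %in% universe, , drop = FALSE]
  scores[hit$gene] <- hit$avg_logFC
  scores
}

#' Wilcoxon gene-set enrichment of marker scores
#'
#' For each gene set, a one-sided Wilcoxon rank-sum test compares the scores
#' of the set's genes (intersected with the universe) against the scores of
#' all other universe genes, alternative: set scores greater. Being
#' rank-based, the result is invariant to monotone transformations of the
#' scores. BH correction is applied across the tested pathways. Sets with
#' fewer than 2 members in the universe are skipped and listed in the
#' `skipped` attribute.
#'
#' @param scores named numeric vector covering the universe (e.g. from
#'   [marker_scores()]).
#' @param sets a [read_gmt()] collection (or plain named list of gene ids).
#' @param universe gene universe; defaults to `names(scores)`.
#' @return `data.frame` with columns `pathway`, `n_genes_in_set`,
#'   `statistic` (Mann-Whitney U of the set genes), `p_value`, `q_value`.
#' @export
wilcoxon_enrichment <- function(scores, sets, universe = names(scores)) {
  .assert(length(universe) > 0, "universe must be non-empty")
  .assert(all(universe %in% names(scores)),
          "scores must cover every universe gene")
  s <- scores[universe]
  X <- matrix(s, ncol = 1, dimnames = list(universe, "score"))
  rt <- .ranks_and_ties(X)
  skipped <- character()
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], universe)
    if (length(members) < 2 || length(members) >= length(universe)) {
      skipped <<- c(skipped, nm)
      return(NULL)
    }
    idx <- match(members, universe)
    test <- .ranksum_test(X, idx, "greater", rt = rt)
    data.frame(pathway = nm, n_genes_in_set = length(members),
               statistic = unname(test$statistic), p_value = test$p_value,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(pathway = character(), n_genes_in_set = integer(),
                      statistic = numeric(), p_value = numeric(),
                      q_value = numeric(), stringsAsFactors = FALSE)
  } else {
    res$q_value <- fdr_correct(res$p_value)
    res <- res[order(res$p_value, res$pathway), ]
    rownames(res) <- NULL
  }
  attr(res, "skipped") <- skipped
  res
}

#' Module-pathway membership counts
#'
#' Counts, for one gene module, how many of its genes fall in each pathway,
#' and drops pathways with fewer than `min_genes` module genes. Deliberately
#' reported without p-values: these are descriptive overlap counts, not a
#' statistical test.
#'
#' @param module_genes character vector of one module's gene ids.
#' @param sets gene-set collection.
#' @param min_genes minimum overlap to report (default 3).
#' @return `data.frame` with columns `pathway`, `n_genes`, sorted by
#'   decreasing count.
#' @export
module_pathway_counts <- function(module_genes, sets, min_genes = 3) {
  counts <- vapply(sets, function(s) length(intersect(module_genes, s)),
                   integer(1))
  keep <- counts >= min_genes
  res <- data.frame(pathway = names(counts)[keep],
                    n_genes = unname(counts[keep]),
                    stringsAsFactors = FALSE)
  res <- res[order(-res$n_genes, res$pathway), ]
  rownames(res) <- NULL
  res
}
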