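# Module-cluster inference: per-cluster eigengene t-statistics with a
# label-permutation null, and leave-cluster-out intramodular connectivity
# change with a matched random-cell-drop null; BH FDR control on both.

.T_CAP <- 1e10   # sentinel for infinite t (cluster sd 0, nonzero numerator)

## Vectorized clusters x modules one-sample t-statistics of eigengene scores:
## cluster mean against the all-cell mean, cluster sd (n-1) / sqrt(n_c).
.tstat_matrix <- function(E, lab) {
  sums <- rowsum(E, lab)
  sums2 <- rowsum(E^2, lab)
  n <- as.vector(table(lab)[rownames(sums)])
  means <- sums / n
  vars <- (sums2 - n * means^2) / pmax(n - 1, 1)
  vars <- pmax(vars, 0)
  pop <- colMeans(E)
  num <- sweep(means, 2L, pop)
  se <- sqrt(vars) / sqrt(n)
  t <- num / se
  t[se == 0 & num == 0] <- 0
  t[se == 0 & num > 0] <- .T_CAP
  t[se == 0 & num < 0] <- -.T_CAP
  t
}

#' Per-cluster module eigengene t-statistics
#'
#' For each (cluster, module) pair, a one-sample t-statistic of the cluster's
#' eigengene scores against the whole-atlas mean score:
#' `t = (mean_cluster - mean_all) / (sd_cluster / sqrt(n_cluster))`, with the
#' n-1 sd. A zero cluster sd with nonzero numerator is recorded as a capped
#' sentinel (1e10) and flagged in the `capped` attribute.
#'
#' @param eigengenes cells x modules eigengene matrix.
#' @param labels per-cell cluster labels (every cluster >= 2 cells).
#' @return clusters x modules matrix of t-statistics.
#' @export
cluster_module_tstats <- function(eigengenes, labels) {
  E <- .as_dense(eigengenes)
  lab <- .check_labels(labels, rownames(E))
  t <- .tstat_matrix(E, lab)
  attr(t, "capped") <- abs(t) >= .T_CAP
  t
}

#' Permutation test of cluster-module association
#'
#' The observed t-statistics of [cluster_module_tstats()] are referred to a
#' null built by permuting cluster labels over cells (cluster sizes
#' preserved) and recomputing all statistics per permutation. The default
#' two-sided p-value is the fraction of permutations with `|t*| >= |t|`
#' (literal count over `n_perm`, no +1 smoothing unless `smooth = TRUE`);
#' BH correction is applied jointly across all (cluster, module) pairs.
#'
#' @param eigengenes cells x modules eigengene matrix.
#' @param labels per-cell cluster labels.
#' @param n_perm number of permutations (>= 100; default 1000).
#' @param seed integer seed for reproducibility.
#' @param sided `"two"` (default) or `"one"` (alternative: cluster mean
#'   above the population mean).
#' @param smooth if `TRUE`, use the (count + 1) / (n_perm + 1) estimator.
#' @return `data.frame` with columns `cluster`, `module`, `t`, `p_perm`,
#'   `q_fdr`, `n_cells`, `n_perm`.
#' @export
permutation_association <- function(eigengenes, labels, n_perm = 1000,
                                    seed = NULL, sided = c("two", "one"),
                                    smooth = FALSE) {
  sided <- match.arg(sided)
  .assert(n_perm >= 100, "n_perm must be at least 100 (unstable tails below)")
  E <- .as_dense(eigengenes)
  lab <- .check_labels(labels, rownames(E))
  if (!is.null(seed)) set.seed(seed)
  t_obs <- .tstat_matrix(E, lab)
  ref <- if (sided == "two") abs(t_obs) else t_obs
  exceed <- matrix(0L, nrow(t_obs), ncol(t_obs))
  n <- nrow(E)
  for (b in seq_len(n_perm)) {
    t_null <- .tstat_matrix(E[sample.int(n), , drop = FALSE], lab)
    cmp <- if (sided == "two") abs(t_null) else t_null
    exceed <- exceed + (cmp >= ref)
  }
  p <- if (smooth) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  n_cells <- as.vector(table(lab)[rownames(t_obs)])
  res <- data.frame(
    cluster = rep(rownames(t_obs), times = ncol(t_obs)),
    module = rep(colnames(t_obs), each = nrow(t_obs)),
    t = as.vector(t_obs),
    p_perm = as.vector(p),
    n_cells = rep(n_cells, times = ncol(t_obs)),
    n_perm = n_perm,
    stringsAsFactors = FALSE
  )
  res$q_fdr <- fdr_correct(res$p_perm)
  res <- res[order(res$module, res$cluster),
             c("cluster", "module", "t", "p_perm", "q_fdr",
               "n_cells", "n_perm")]
  rownames(res) <- NULL
  res
}

#' Intramodular connectivity on a cell subset
#'
#' Recomputes the biweight midcorrelation of one module's genes on the given
#' cells, forms the unsigned soft-power adjacency `|cor|^beta`, and returns
#' the total intramodular connectivity: the sum of off-diagonal adjacency.
#'
#' @param norm cells x genes normalized expression restricted to one module's
#'   genes.
#' @param cells optional cell ids / indices to keep (default all).
#' @param beta soft-threshold power (default 2, matching the main network).
#' @param max_p_outliers bicor outlier cap (default 0.05).
#' @return total intramodular connectivity (non-negative scalar).
#' @export
module_connectivity <- function(norm, cells = NULL, beta = 2,
                                max_p_outliers = 0.05) {
  X <- .as_dense(norm)
  if (!is.null(cells)) X <- X[cells, , drop = FALSE]
  .assert(nrow(X) >= 3, "need at least 3 cells after subsetting")
  .assert(ncol(X) >= 2, "need at least 2 genes")
  C <- bicor_matrix(X, max_p_outliers = max_p_outliers)
  A <- abs(C)^beta
  sum(A) - sum(diag(A))
}

#' Leave-cluster-out connectivity sensitivity
#'
#' For every (cluster, module) pair, the module's total intramodular
#' connectivity is computed on all cells (`K_full`) and with the cluster's
#' cells removed (`K_drop`); the statistic is `delta = K_full - K_drop`,
#' recomputed from expression (not rescaled). The null drops the same number
#' of uniformly random cells (from all cells by default) `n_perm` times and
#' records the null deltas; the one-sided p-value is the fraction of
#' permutations whose delta is strictly greater than the observed one, so
#' small p flags clusters whose removal reduces connectivity more than a
#' random drop of equal size. BH correction is applied jointly across pairs.
#'
#' @param norm cells x genes normalized expression covering the network genes.
#' @param assignment a `module_assignment` (module 0 excluded).
#' @param labels per-cell cluster labels.
#' @param beta soft-threshold power of the main network (default 2).
#' @param n_perm random drops per cluster size (default 1000).
#' @param seed integer seed.
#' @param drop_pool `"all"` (default: random drops sampled from all cells,
#'   focal cluster included) or `"other"` (sampled from non-focal cells).
#' @param smooth if `TRUE`, (count + 1) / (n_perm + 1) p-values.
#' @param max_p_outliers bicor outlier cap (default 0.05).
#' @return `data.frame` with columns `cluster`, `module`, `K_full`, `K_drop`,
#'   `delta`, `p_perm`, `q_fdr`, `n_perm`.
#' @export
connectivity_drop <- function(norm, assignment, labels, beta = 2,
                              n_perm = 1000, seed = NULL,
                              drop_pool = c("all", "other"), smooth = FALSE,
                              max_p_outliers = 0.05) {
  drop_pool <- match.arg(drop_pool)
  X <- .as_dense(norm)
  lab <- .check_labels(labels, rownames(X), min_cells = 1L)
  module <- if (inherits(assignment, "module_assignment")) {
    assignment$module
  } else {
    assignment
  }
  mods <- sort(unique(module[module > 0]))
  .assert(length(mods) >= 1, "no non-zero modules")
  clusters <- sort(unique(lab))
  n <- nrow(X)
  sizes <- stats::setNames(as.vector(table(lab)[clusters]), clusters)
  .assert(all(n - sizes >= 3),
          "every cluster's removal must leave at least 3 cells")
  if (!is.null(seed)) set.seed(seed)

  gene_sets <- lapply(mods, function(m) names(module)[module == m])
  K_of <- function(rows) {
    vapply(gene_sets, function(g) {
      module_connectivity(X[rows, g, drop = FALSE], beta = beta,
                          max_p_outliers = max_p_outliers)
    }, numeric(1))
  }
  K_full <- K_of(seq_len(n))

  K_drop <- matrix(NA_real_, length(clusters), length(mods),
                   dimnames = list(clusters, paste0("ME", mods)))
  for (cl in clusters) {
    K_drop[cl, ] <- K_of(which(lab != cl))
  }
  delta <- sweep(-K_drop, 2L, K_full, `+`)   # K_full - K_drop

  ## null: per distinct cluster size, n_perm random drops of that many cells
  exceed <- matrix(0L, length(clusters), length(mods),
                   dimnames = dimnames(K_drop))
  for (sz in unique(sizes)) {
    cls <- names(sizes)[sizes == sz]
    null_delta <- matrix(NA_real_, n_perm, length(mods))
    if (drop_pool == "all") {
      for (b in seq_len(n_perm)) {
        keep <- sample.int(n, n - sz)
        null_delta[b, ] <- K_full - K_of(keep)
      }
      for (cl in cls) {
        exceed[cl, ] <- colSums(sweep(null_delta, 2L, delta[cl, ], `>`))
      }
    } else {
      for (cl in cls) {
        pool <- which(lab != cl)
        for (b in seq_len(n_perm)) {
          keep <- c(which(lab == cl), sample(pool, length(pool) - sz))
          null_delta[b, ] <- K_full - K_of(keep)
        }
        exceed[cl, ] <- colSums(sweep(null_delta, 2L, delta[cl, ], `>`))
      }
    }
  }
  p <- if (smooth) (exceed + 1) / (n_perm + 1) else exceed / n_perm
  res <- data.frame(
    cluster = rep(clusters, times = length(mods)),
    module = rep(paste0("ME", mods), each = length(clusters)),
    K_full = rep(K_full, each = length(clusters)),
    K_drop = as.vector(K_drop),
    delta = as.vector(delta),
    p_perm = as.vector(p),
    n_perm = n_perm,
    stringsAsFactors = FALSE
  )
  res$q_fdr <- fdr_correct(res$p_perm)
  res <- res[order(res$module, res$cluster),
             c("cluster", "module", "K_full", "K_drop", "delta",
               "p_perm", "q_fdr", "n_perm")]
  rownames(res) <- NULL
  res
}
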