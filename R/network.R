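# Weighted gene co-expression network construction: biweight midcorrelation
# with per-side outlier capping, scale-free soft-threshold selection,
# topological overlap, dendrogram module detection, module eigengenes and
# eigengene-based module merging.

## Per-gene biweight transform used column-wise by bicor_matrix().
## Returns the weighted centered column (not yet normalized) or, when the
## gene's MAD is zero, the plain centered column (Pearson fallback).
.bicor_column <- function(x, max_p_outliers) {
  med <- stats::median(x)
  md <- stats::mad(x)          # scaled MAD (consistent with the usual bicor)
  if (md == 0) {
    return(list(a = x - mean(x), fallback = TRUE))
  }
  u <- (x - med) / (9 * md)
  if (max_p_outliers < 0.5) {
    ## cap each side so at most max_p_outliers of observations per side get
    ## zero weight: rescale a side when its (1 - maxP) quantile passes |u|=1
    q_low <- stats::quantile(u, probs = max_p_outliers, names = FALSE)
    q_high <- stats::quantile(u, probs = 1 - max_p_outliers, names = FALSE)
    if (q_low < -1) u[u < 0] <- u[u < 0] / (-q_low)
    if (q_high > 1) u[u > 0] <- u[u > 0] / q_high
  }
  w <- (1 - u^2)^2 * (abs(u) < 1)
  list(a = (x - med) * w, fallback = FALSE)
}

#' Biweight midcorrelation matrix
#'
#' Robust gene-gene correlation: each gene's observations are weighted with
#' Tukey biweights built from median/MAD-standardized values
#' `u = (x - median) / (9 * mad)`; the correlation is the cross-product of
#' the weighted centered vectors after unit normalization. `max_p_outliers`
#' caps, per side of the median, the fraction of observations that may
#' receive zero weight (the side's `u` values are rescaled so the capping
#' quantile maps to 1). Genes with zero MAD fall back to Pearson for all
#' their pairs (flagged); constant genes get correlation 0 (flagged) and a
#' unit diagonal.
#'
#' @param norm cells x genes matrix of normalized expression restricted to
#'   the network genes (>= 3 cells, >= 2 genes).
#' @param max_p_outliers per-side outlier fraction cap (default 0.05).
#' @return genes x genes correlation matrix with attributes
#'   `fallback` (logical per gene: Pearson fallback used) and
#'   `constant` (logical per gene: zero variance, correlations set to 0).
#' @export
bicor_matrix <- function(norm, max_p_outliers = 0.05) {
  X <- .as_dense(norm)
  .assert(nrow(X) >= 3, "need at least 3 cells")
  .assert(ncol(X) >= 2, "need at least 2 genes")
  .assert(max_p_outliers >= 0 && max_p_outliers <= 0.5,
          "max_p_outliers must be in [0, 0.5]")
  p <- ncol(X)
  A <- matrix(0, nrow(X), p)
  fallback <- logical(p)
  constant <- logical(p)
  for (j in seq_len(p)) {
    col <- .bicor_column(X[, j], max_p_outliers)
    nrm <- sqrt(sum(col$a^2))
    if (nrm == 0) {
      constant[j] <- TRUE       # zero variance: undefined, recorded as 0
    } else {
      A[, j] <- col$a / nrm
    }
    fallback[j] <- col$fallback
  }
  C <- crossprod(A)
  C <- pmin(pmax(C, -1), 1)
  diag(C) <- 1
  dimnames(C) <- list(colnames(X), colnames(X))
  names(fallback) <- names(constant) <- colnames(X)
  attr(C, "fallback") <- fallback
  attr(C, "constant") <- constant
  C
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power, connectivities `k_i = sum_{j != i} |cor_ij|^beta`
#' are computed, `log10(k)` is binned into `n_bins` equal-width bins, and
#' `log10(mean bin frequency)` is regressed on `log10(mean bin k)`. The
#' signed fit is `-sign(slope) * R^2`; the chosen power is the smallest with
#' signed fit at or above `r2_target`, otherwise the power maximizing the
#' signed fit. An explicit `override` bypasses the choice (the fit table is
#' still returned).
#'
#' @param cor gene correlation matrix.
#' @param candidate_powers powers to evaluate (default 1..10).
#' @param n_bins histogram bins for the degree distribution (default 10).
#' @param r2_target signed-fit target (default 0.8).
#' @param override if non-`NULL`, the returned power regardless of fit.
#' @return list with `power` and `fit_table` (`data.frame` of power, slope,
#'   r_squared, signed_fit, mean_k, max_k).
#' @export
pick_soft_threshold <- function(cor, candidate_powers = 1:10, n_bins = 10,
                                r2_target = 0.8, override = NULL) {
  .assert(all(candidate_powers > 0), "candidate powers must be positive")
  S <- abs(cor)
  diag(S) <- 0
  rows <- lapply(candidate_powers, function(beta) {
    k <- colSums(S^beta)
    fit <- .scale_free_fit(k, n_bins)
    data.frame(power = beta, slope = fit$slope, r_squared = fit$r2,
               signed_fit = fit$signed, mean_k = mean(k), max_k = max(k))
  })
  fit_table <- do.call(rbind, rows)
  if (!is.null(override)) {
    return(list(power = override, fit_table = fit_table))
  }
  .assert(!all(is.na(fit_table$signed_fit)),
          "degenerate connectivity distribution; supply the power manually via override")
  ok <- which(!is.na(fit_table$signed_fit) & fit_table$signed_fit >= r2_target)
  power <- if (length(ok)) {
    fit_table$power[ok[1]]
  } else {
    fit_table$power[which.max(fit_table$signed_fit)]
  }
  list(power = power, fit_table = fit_table)
}

.scale_free_fit <- function(k, n_bins) {
  k <- k[k > 0]
  if (length(k) < 2 || diff(range(k)) < 1e-12) {
    return(list(slope = NA_real_, r2 = NA_real_, signed = NA_real_))
  }
  lk <- log10(k)
  breaks <- seq(min(lk), max(lk), length.out = n_bins + 1)
  bin <- cut(lk, breaks = breaks, include.lowest = TRUE)
  freq <- tapply(lk, bin, length)
  kmean <- tapply(k, bin, mean)
  keep <- !is.na(freq) & freq > 0
  if (sum(keep) < 3) {
    return(list(slope = NA_real_, r2 = NA_real_, signed = NA_real_))
  }
  xs <- log10(kmean[keep])
  ys <- log10(freq[keep] / length(k))
  fit <- stats::lm(ys ~ xs)
  slope <- unname(stats::coef(fit)[2])
  r2 <- summary(fit)$r.squared
  list(slope = slope, r2 = r2, signed = -sign(slope) * r2)
}

#' Soft-power adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor_ij|^beta`, unit diagonal.
#'
#' @param cor correlation matrix.
#' @param beta soft-threshold power.
#' @return adjacency matrix in `[0, 1]`.
#' @export
adjacency_matrix <- function(cor, beta) {
  .assert(beta > 0, "beta must be positive")
  A <- abs(cor)^beta
  diag(A) <- 1
  A
}

#' Topological overlap similarity
#'
#' Unsigned TOM: with off-diagonal adjacency `a`,
#' `k_i = sum_{u != i} a_iu`, `L_ij = sum_{u != i,j} a_iu a_uj`,
#' `TOM_ij = (L_ij + a_ij) / (min(k_i, k_j) + 1 - a_ij)` for `i != j`, and
#' `TOM_ii = 1`. The module-detection dissimilarity is `1 - TOM`.
#'
#' @param adj adjacency matrix with entries in `[0, 1]`.
#' @return TOM similarity matrix in `[0, 1]` with unit diagonal.
#' @export
tom_similarity <- function(adj) {
  .assert(all(adj >= -1e-12 & adj <= 1 + 1e-12),
          "adjacency entries must lie in [0, 1]")
  A <- as.matrix(adj)
  .assert(nrow(A) == ncol(A) && max(abs(A - t(A))) < 1e-10,
          "adjacency must be square and symmetric")
  diag(A) <- 0
  L <- A %*% A                     # zero diagonal of A excludes u = i and u = j
  k <- rowSums(A)
  kmin <- outer(k, k, pmin)
  TOM <- (L + A) / (kmin + 1 - A)
  diag(TOM) <- 1
  TOM <- pmin(pmax(TOM, 0), 1)
  dimnames(TOM) <- dimnames(adj)
  TOM
}

#' Detect gene modules by cutting the TOM dendrogram
#'
#' Average-linkage hierarchical clustering of the dissimilarity followed by a
#' simplified dynamic cut: the static cut height is placed at the midpoint of
#' the largest gap in the sorted merge heights, which separates
#' branch-internal merges from the background band where unrelated genes
#' attach. `deep_split` (0..4, mapping to quantiles 0.95, 0.90, 0.85, 0.80,
#' 0.75 of the merge heights) caps how high the gap may start: larger values
#' restrict the cut to lower heights, splitting more aggressively. When no
#' gap exists (all merge heights equal), nothing is cohesive and every gene
#' is left unassigned. Branches smaller than `min_cluster_size` fall into
#' module 0 (unassigned). Modules are numbered by decreasing size.
#'
#' @param dissim square symmetric dissimilarity matrix (e.g. `1 - TOM`).
#' @param min_cluster_size smallest admissible module (default 15).
#' @param deep_split split aggressiveness, integer 0..4 (default 2).
#' @return list of class `module_assignment` with `module` (named integer
#'   vector, gene -> module number, 0 = unassigned), `sizes`, `cut_height`,
#'   `merge_heights` and the `hclust` tree.
#' @export
cut_modules <- function(dissim, min_cluster_size = 15, deep_split = 2) {
  D <- as.matrix(dissim)
  .assert(nrow(D) == ncol(D) && max(abs(D - t(D))) < 1e-8,
          "dissimilarity must be square and symmetric")
  .assert(deep_split %in% 0:4, "deep_split must be an integer in 0..4")
  genes <- colnames(D) %||% paste0("g", seq_len(ncol(D)))
  if (ncol(D) < min_cluster_size) {
    warning("fewer genes than min_cluster_size; all genes unassigned")
    module <- stats::setNames(rep(0L, ncol(D)), genes)
    return(structure(list(module = module, sizes = integer(),
                          cut_height = NA_real_, merge_heights = numeric(),
                          tree = NULL), class = "module_assignment"))
  }
  hc <- stats::hclust(stats::as.dist(D), method = "average")
  heights <- hc$height
  q <- c(0.95, 0.90, 0.85, 0.80, 0.75)[deep_split + 1]
  qcap <- stats::quantile(heights, probs = q, names = FALSE)
  hs <- sort(heights)
  gaps <- diff(hs)
  eligible <- which(hs[-length(hs)] <= qcap)
  tiny <- 1e-8 * max(1, abs(hs[length(hs)]))
  if (length(eligible) == 0 || max(gaps[eligible]) <= tiny) {
    h <- hs[1] - tiny              # no separating gap: leave all unassigned
  } else {
    i <- eligible[which.max(gaps[eligible])]
    h <- (hs[i] + hs[i + 1]) / 2
  }
  raw <- stats::cutree(hc, h = h)
  sizes <- table(raw)
  keep <- names(sizes)[sizes >= min_cluster_size]
  module <- integer(length(raw))
  if (length(keep)) {
    kept_sizes <- sort(sizes[keep], decreasing = TRUE)
    for (r in seq_along(kept_sizes)) {
      module[raw == as.integer(names(kept_sizes)[r])] <- r
    }
  }
  names(module) <- genes
  out_sizes <- if (length(keep)) {
    as.integer(sort(sizes[keep], decreasing = TRUE))
  } else integer()
  structure(list(module = module, sizes = out_sizes, cut_height = h,
                 merge_heights = heights, tree = hc),
            class = "module_assignment")
}

#' Module eigengenes
#'
#' For each module, member genes are standardized over cells (mean 0, sd 1;
#' zero-variance genes dropped with a warning) and the first principal
#' component over cells is taken as the module eigengene: unit norm over
#' cells, sign-aligned so its correlation with the module's mean
#' standardized expression is non-negative. Module 0 (unassigned) is
#' excluded.
#'
#' @param norm cells x genes normalized expression covering the network genes.
#' @param assignment a `module_assignment` (or named gene -> module vector).
#' @return list with `eigengenes` (cells x modules matrix, columns
#'   `ME<number>`) and `var_explained` (per-module first-PC variance
#'   fraction).
#' @export
module_eigengenes <- function(norm, assignment) {
  module <- if (inherits(assignment, "module_assignment")) {
    assignment$module
  } else {
    assignment
  }
  X <- .as_dense(norm)
  mods <- sort(unique(module[module > 0]))
  .assert(length(mods) >= 1, "no non-zero modules in assignment")
  E <- matrix(NA_real_, nrow(X), length(mods),
              dimnames = list(rownames(X), paste0("ME", mods)))
  varexp <- stats::setNames(numeric(length(mods)), paste0("ME", mods))
  for (mi in seq_along(mods)) {
    genes <- names(module)[module == mods[mi]]
    .assert(all(genes %in% colnames(X)),
            "assignment references genes absent from the expression matrix")
    Z <- X[, genes, drop = FALSE]
    sds <- apply(Z, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sprintf("module %d: dropping %d zero-variance gene(s) from the eigengene",
                      mods[mi], sum(sds == 0)))
      Z <- Z[, sds > 0, drop = FALSE]
    }
    .assert(ncol(Z) >= 2, "module %d has fewer than 2 usable genes", mods[mi])
    Z <- scale(Z)
    sv <- svd(Z)
    e <- sv$u[, 1]
    if (stats::cor(e, rowMeans(Z)) < 0) e <- -e
    E[, mi] <- e
    varexp[mi] <- sv$d[1]^2 / sum(sv$d^2)
  }
  list(eigengenes = E, var_explained = varexp)
}

#' Merge modules with correlated eigengenes
#'
#' Eigengene dissimilarity `1 - cor` is clustered with average linkage;
#' modules joined below `dissim_cutoff` are merged, eigengenes recomputed,
#' and the procedure iterates until no pair falls below the cutoff. Modules
#' are renumbered by decreasing size.
#'
#' @param norm cells x genes normalized expression covering the network genes.
#' @param assignment a `module_assignment`.
#' @param dissim_cutoff eigengene dissimilarity below which modules merge
#'   (default 0.35).
#' @param max_iter safety bound on merge iterations.
#' @return list with the merged `assignment` (class `module_assignment`),
#'   final `eigengenes` and `var_explained`.
#' @export
merge_modules <- function(norm, assignment, dissim_cutoff = 0.35,
                          max_iter = 25) {
  .assert(inherits(assignment, "module_assignment"),
          "assignment must come from cut_modules()")
  module <- assignment$module
  me <- NULL
  for (it in seq_len(max_iter)) {
    me <- module_eigengenes(norm, module)
    M <- ncol(me$eigengenes)
    if (M < 2) break
    d <- 1 - stats::cor(me$eigengenes)
    hc <- stats::hclust(stats::as.dist(d), method = "average")
    grp <- stats::cutree(hc, h = dissim_cutoff)
    if (max(grp) == M) break          # every module is its own group
    mods <- as.integer(sub("^ME", "", colnames(me$eigengenes)))
    new_of_old <- stats::setNames(grp, mods)
    remap <- integer(length(module))
    nz <- module > 0
    remap[nz] <- new_of_old[as.character(module[nz])]
    module <- stats::setNames(remap, names(module))
    module <- .renumber_by_size(module)
  }
  sizes <- as.integer(sort(table(module[module > 0]), decreasing = TRUE))
  merged <- structure(list(module = module, sizes = sizes,
                           cut_height = assignment$cut_height,
                           merge_heights = assignment$merge_heights,
                           tree = assignment$tree),
                      class = "module_assignment")
  me <- module_eigengenes(norm, module)
  list(assignment = merged, eigengenes = me$eigengenes,
       var_explained = me$var_explained)
}

.renumber_by_size <- function(module) {
  sizes <- sort(table(module[module > 0]), decreasing = TRUE)
  new <- integer(length(module))
  for (r in seq_along(sizes)) {
    new[module == as.integer(names(sizes)[r])] <- r
  }
  stats::setNames(new, names(module))
}
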