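# Independent brute-force oracles and shared fixtures for the test suite.

## Literal scalar transcription of the biweight midcorrelation of two
## vectors, including the per-side outlier cap. Kept loop-based and
## pair-at-a-time, independent of the vectorized matrix implementation.
bicor_loop <- function(x, y, max_p_outliers = 0.05) {
  weight_vec <- function(v) {
    med <- median(v)
    md <- mad(v)
    if (md == 0) return(NULL)
    u <- (v - med) / (9 * md)
    if (max_p_outliers < 0.5) {
      ql <- quantile(u, max_p_outliers, names = FALSE)
      qh <- quantile(u, 1 - max_p_outliers, names = FALSE)
      for (i in seq_along(u)) {
        if (ql < -1 && u[i] < 0) u[i] <- u[i] / (-ql)
        if (qh > 1 && u[i] > 0) u[i] <- u[i] / qh
      }
    }
    a <- numeric(length(v))
    for (i in seq_along(v)) {
      w <- if (abs(u[i]) < 1) (1 - u[i]^2)^2 else 0
      a[i] <- (v[i] - med) * w
    }
    a
  }
  a <- weight_vec(x)
  b <- weight_vec(y)
  if (is.null(a)) a <- x - mean(x)   # Pearson fallback side
  if (is.null(b)) b <- y - mean(y)
  num <- 0; dx <- 0; dy <- 0
  for (i in seq_along(x)) {
    num <- num + a[i] * b[i]
    dx <- dx + a[i]^2
    dy <- dy + b[i]^2
  }
  num / sqrt(dx * dy)
}

## Triple-loop transcription of the unsigned topological overlap definition.
tom_loop <- function(adj) {
  n <- nrow(adj)
  A <- adj
  diag(A) <- 0
  TOM <- diag(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      L <- 0
      for (u in seq_len(n)) {
        if (u != i && u != j) L <- L + A[i, u] * A[u, j]
      }
      ki <- sum(A[i, -i])
      kj <- sum(A[j, -j])
      TOM[i, j] <- (L + A[i, j]) / (min(ki, kj) + 1 - A[i, j])
    }
  }
  TOM
}

## Exhaustive two-sided rank-sum p-value by enumerating every assignment of
## group labels (oracle for the normal-approximation / exact code path).
ranksum_enum_p <- function(values, in_idx, alternative = "two.sided") {
  N <- length(values)
  n1 <- length(in_idx)
  r <- rank(values)
  mu <- n1 * (N - n1) / 2
  obs <- sum(r[in_idx]) - n1 * (n1 + 1) / 2
  combs <- combn(N, n1)
  stats <- apply(combs, 2L, function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2)
  if (alternative == "two.sided") {
    mean(abs(stats - mu) >= abs(obs - mu) - 1e-12)
  } else {
    mean(stats >= obs - 1e-12)
  }
}

## Small standard atlas used across tests: 3 clusters, planted markers and
## two single-cluster modules, mito genes and doublets.
small_atlas <- function(seed = 7, n_per_cluster = 150) {
  design <- atlas_design(
    n_cells_per_cluster = rep(n_per_cluster, 3),
    n_genes = 120,
    baseline_mean = 0.6,
    dispersion = 2,
    marker_plan = data.frame(gene = 1:3, cluster = 1:3,
                             in_fraction = 0.9, out_fraction = 0.05,
                             fold_change = 8),
    module_plan = list(
      list(genes = 11:30, clusters = 1, factor_sd = 1, loading = 2),
      list(genes = 31:50, clusters = 2, factor_sd = 1, loading = 2)
    ),
    mito_gene_indices = 111:120,
    doublet_rate = 0.04,
    seed = seed
  )
  generate_atlas(design)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)
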