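# Internal shared helpers: input checks, rank-sum machinery, detection fractions.

`%||%` <- function(a, b) if (is.null(a)) b else a

.assert <- function(cond, ...) {
  if (!isTRUE(cond)) stop(sprintf(...), call. = FALSE)
}

## Coerce a counts/expression container to a base dense matrix (cells x genes).
.as_dense <- function(x) {
  if (inherits(x, "Matrix")) as.matrix(x) else as.matrix(x)
}

## Per-cluster detection fractions: fraction of cells with value > 0,
## one row per cluster, one column per gene.
.detection_fractions <- function(mat, labels) {
  labels <- as.character(labels)
  detected <- .as_dense(mat) > 0
  agg <- rowsum(detected * 1, labels)
  sizes <- as.vector(table(labels)[rownames(agg)])
  agg / sizes
}

## Rank matrix and tie-correction terms, computed once per expression matrix
## and reused across clusters (ranks do not depend on the grouping).
.ranks_and_ties <- function(X) {
  R <- apply(X, 2L, rank)
  tiecor <- apply(X, 2L, function(col) {
    tt <- table(col)
    sum(tt^3 - tt)
  })
  list(R = R, tiecor = tiecor)
}

## Vectorized Wilcoxon rank-sum across the columns of X for one grouping.
## Normal approximation with tie correction (no continuity correction);
## exact enumeration of all choose(N, n1) group assignments when N < 10.
## alternative: "two.sided" or "greater" (first group stochastically larger).
.ranksum_test <- function(X, in_idx, alternative = c("two.sided", "greater"),
                          rt = NULL) {
  alternative <- match.arg(alternative)
  X <- as.matrix(X)
  N <- nrow(X)
  n1 <- length(in_idx)
  n2 <- N - n1
  .assert(n1 >= 1 && n2 >= 1, "both groups must be non-empty")
  if (is.null(rt)) rt <- .ranks_and_ties(X)
  R <- rt$R
  rank_sum <- if (n1 == 1L) R[in_idx, ] else colSums(R[in_idx, , drop = FALSE])
  W <- rank_sum - n1 * (n1 + 1) / 2   # Mann-Whitney U for group 1
  mu <- n1 * n2 / 2
  if (N < 10) {
    combs <- utils::combn(N, n1)
    p <- vapply(seq_len(ncol(X)), function(j) {
      r <- R[, j]
      stats_all <- colSums(matrix(r[combs], nrow = n1)) - n1 * (n1 + 1) / 2
      if (alternative == "two.sided") {
        mean(abs(stats_all - mu) >= abs(W[j] - mu) - 1e-12)
      } else {
        mean(stats_all >= W[j] - 1e-12)
      }
    }, numeric(1))
  } else {
    sigma2 <- (n1 * n2 / 12) * ((N + 1) - rt$tiecor / (N * (N - 1)))
    sigma <- sqrt(pmax(sigma2, 0))
    z <- ifelse(sigma > 0, (W - mu) / sigma, 0)
    p <- if (alternative == "two.sided") {
      ifelse(sigma > 0, 2 * stats::pnorm(-abs(z)), 1)
    } else {
      ifelse(sigma > 0, stats::pnorm(z, lower.tail = FALSE), 1)
    }
    p <- pmin(p, 1)
  }
  list(statistic = W, p_value = unname(p))
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up false discovery rate adjustment of a vector of p-values.
#' Thin validated wrapper around [stats::p.adjust()]; missing or out-of-range
#' p-values are rejected rather than propagated.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @param method adjustment method, only `"BH"` is supported.
#' @return numeric vector of q-values, same length and names as `p`.
#' @export
fdr_correct <- function(p, method = "BH") {
  .assert(identical(method, "BH"), "only method = 'BH' is supported")
  .assert(is.numeric(p), "p must be numeric")
  .assert(!anyNA(p), "NA/NaN p-values are not allowed")
  .assert(all(p >= 0 & p <= 1), "p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
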