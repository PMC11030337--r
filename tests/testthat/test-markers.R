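# Marker detection: rank-sum markers against enumeration and wilcox.test
# oracles, the strict 60/10 specificity rule, best-marker selection,
# restricted-gene queries.

test_that("six-cell rank-sum toy matches the exhaustive enumeration oracle", {
  values <- c(5, 6, 7, 1, 2, 3)
  X <- matrix(values, ncol = 1, dimnames = list(paste0("c", 1:6), "g"))
  res <- scmodnet:::.ranksum_test(X, in_idx = 1:3, alternative = "two.sided")
  expect_equal(res$p_value, ranksum_enum_p(values, 1:3))
  expect_equal(res$p_value, 2 / 20)    # perfect separation of 3 vs 3
  ## and with ties
  tied <- c(5, 5, 7, 1, 5, 3)
  Xt <- matrix(tied, ncol = 1, dimnames = list(paste0("c", 1:6), "g"))
  rest <- scmodnet:::.ranksum_test(Xt, in_idx = 1:3, alternative = "two.sided")
  expect_equal(rest$p_value, ranksum_enum_p(tied, 1:3))
})

test_that("normal-approximation p-values agree with wilcox.test", {
  set.seed(42)
  X <- matrix(rnorm(60 * 25), nrow = 60,
              dimnames = list(paste0("c", 1:60), paste0("g", 1:25)))
  X[, 1:5] <- X[, 1:5] + rep(c(1.2, 0), c(20, 40))   # some signal
  inside <- 1:20
  res <- scmodnet:::.ranksum_test(X, inside, "two.sided")
  ref <- vapply(seq_len(ncol(X)), function(j) {
    wilcox.test(X[inside, j], X[-inside, j], exact = FALSE,
                correct = FALSE)$p.value
  }, numeric(1))
  expect_equal(res$p_value, ref, tolerance = 1e-12)
})

test_that("ranksum markers report positive, fold-change-passing genes", {
  a <- small_atlas(seed = 19)
  norm <- log_normalize(a$counts)
  mk <- ranksum_markers(norm, a$labels)
  expect_true(all(mk$avg_logFC >= 0.25))
  expect_true(all(mk$q_value >= mk$p_value))
  ## planted markers recovered for their own cluster with tiny p
  for (r in 1:3) {
    row <- mk[mk$gene == sprintf("gene%04d", r) & mk$cluster == r, ]
    expect_equal(nrow(row), 1L)
    expect_lt(row$p_value, 1e-10)
  }
  ## a gene identical in all cells is never reported
  flat <- norm
  flat[, 5] <- 1
  mk_flat <- ranksum_markers(flat, a$labels)
  expect_false("gene0005" %in% mk_flat$gene)
})

test_that("specificity rule applies strict inequalities at 60/10", {
  ## cluster A: 100 cells, B: 100, C: 100; craft detection patterns exactly
  n <- 100
  lab <- rep(c("A", "B", "C"), each = n)
  mk_gene <- function(fA, fB, fC) {
    c(rep(1, fA * n), rep(0, n - fA * n),
      rep(1, fB * n), rep(0, n - fB * n),
      rep(1, fC * n), rep(0, n - fC * n))
  }
  counts <- cbind(
    pass = mk_gene(0.61, 0.09, 0.09),
    at_in_boundary = mk_gene(0.60, 0.09, 0.09),
    at_out_boundary = mk_gene(0.70, 0.10, 0.05),
    perfect = mk_gene(1, 0, 0)
  )
  rownames(counts) <- paste0("c", seq_len(3 * n))
  res <- specificity_markers(counts, lab)
  expect_setequal(res$gene[res$cluster == "A"], c("pass", "perfect"))
  expect_false("at_in_boundary" %in% res$gene)
  expect_false("at_out_boundary" %in% res$gene)
  ## invariant to count magnitude and cell order
  perm <- sample(nrow(counts))
  res2 <- specificity_markers(counts[perm, ] * 7, lab[perm])
  expect_equal(res2[order(res2$gene), ], res[order(res$gene), ],
               ignore_attr = TRUE)
})

test_that("planted markers with wide margins are recovered", {
  a <- small_atlas(seed = 23)
  res <- specificity_markers(a$counts, a$labels)
  for (r in 1:3) {
    expect_true(any(res$gene == sprintf("gene%04d", r) & res$cluster == r))
  }
})

test_that("best-marker choice maximizes the in/out margin with stated ties", {
  records <- data.frame(
    gene = c("gA", "gB", "gC", "gD"),
    cluster = c("1", "1", "2", "2"),
    pct_in = c(0.90, 0.95, 0.80, 0.80),
    pct_out_max = c(0.05, 0.20, 0.10, 0.10)
  )
  best <- best_marker_per_cluster(records)
  expect_equal(best$gene[best$cluster == "1"], "gA")   # margin .85 > .75
  expect_equal(best$gene[best$cluster == "2"], "gC")   # exact tie -> smaller id
  single <- best_marker_per_cluster(records[1, ])
  expect_equal(single$gene, "gA")
  ## unmarked clusters are listed with NA
  all3 <- best_marker_per_cluster(records, clusters = c("1", "2", "3"))
  expect_true(is.na(all3$gene[all3$cluster == "3"]))
})

test_that("restricted-gene queries flag cluster-specific genes only", {
  a <- small_atlas(seed = 29)
  ## census on clean singlets: doublets smear markers across clusters
  keep <- !a$truth$is_doublet
  a$counts <- a$counts[keep, ]
  a$labels <- a$labels[keep, ]
  q <- celltype_restricted_genes(a$counts, a$labels,
                                 gene_ids = c("gene0001", "gene0060"),
                                 target_cluster = 1)
  expect_true(q$table$restricted[q$table$gene == "gene0001"])
  expect_false(q$table$restricted[q$table$gene == "gene0060"])
  expect_equal(dim(q$fractions), c(2L, 3L))
  empty <- celltype_restricted_genes(a$counts, a$labels, character(), 1)
  expect_equal(nrow(empty$table), 0L)
  expect_error(celltype_restricted_genes(a$counts, a$labels, "nope", 1),
               "nope")
})

test_that("rank-sum p-values are near-uniform on label-permuted data", {
  set.seed(101)
  n <- 120
  X <- matrix(rnorm(n * 600), nrow = n,
              dimnames = list(paste0("c", 1:n), paste0("g", 1:600)))
  inside <- sample(n, 50)
  res <- scmodnet:::.ranksum_test(X, inside, "two.sided")
  ks <- suppressWarnings(ks.test(res$p_value, "punif"))
  expect_lt(unname(ks$statistic), 0.05)
})
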