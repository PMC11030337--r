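# Module-cluster inference: t-statistics, permutation association,
# intramodular connectivity, leave-cluster-out sensitivity, BH correction.

test_that("cluster t-statistics match hand arithmetic", {
  ## cluster A = {2, 4}, cluster B = {-1, -1}: population mean 1
  E <- matrix(c(2, 4, -1, -1), ncol = 1,
              dimnames = list(paste0("c", 1:4), "ME1"))
  lab <- c("A", "A", "B", "B")
  t <- cluster_module_tstats(E, lab)
  expect_equal(t["A", "ME1"], (3 - 1) / (sd(c(2, 4)) / sqrt(2)))
  expect_equal(t["A", "ME1"], 2)
  ## zero-sd cluster with nonzero numerator: capped sentinel, flagged
  expect_equal(t["B", "ME1"], -1e10)
  expect_true(attr(t, "capped")["B", "ME1"])
  ## cluster equal to the population mean gives t = 0
  E0 <- matrix(c(1, 1, 0, 2), ncol = 1,
               dimnames = list(paste0("c", 1:4), "ME1"))
  t0 <- cluster_module_tstats(E0, c("A", "A", "B", "B"))
  expect_equal(t0["A", "ME1"], 0)
  ## permuting cells within a cluster changes nothing
  E2 <- matrix(rnorm(40), ncol = 2,
               dimnames = list(paste0("c", 1:20), c("ME1", "ME2")))
  lab2 <- rep(c("A", "B"), each = 10)
  tref <- cluster_module_tstats(E2, lab2)
  perm <- c(sample(1:10), sample(11:20))
  expect_equal(cluster_module_tstats(E2[perm, ], lab2[perm]), tref,
               ignore_attr = TRUE)
})

test_that("permutation association is seeded, reproducible and calibrated", {
  set.seed(51)
  E <- matrix(rnorm(300 * 3), ncol = 3,
              dimnames = list(paste0("c", 1:300), paste0("ME", 1:3)))
  lab <- sample(rep(1:5, each = 60))
  a1 <- permutation_association(E, lab, n_perm = 200, seed = 99)
  a2 <- permutation_association(E, lab, n_perm = 200, seed = 99)
  expect_identical(a1, a2)
  expect_true(all(a1$p_perm >= 0 & a1$p_perm <= 1))
  expect_true(all(a1$q_fdr >= a1$p_perm))
  expect_error(permutation_association(E, lab, n_perm = 50), "100")
  ## independent eigengene: no pair should be extreme at alpha 0.05 / n tests
  expect_gt(min(a1$q_fdr), 0.05)
})

test_that("a planted single-cluster module is detected by association", {
  design <- atlas_design(
    n_cells_per_cluster = rep(150, 4), n_genes = 150, baseline_mean = 0.6,
    module_plan = list(list(genes = 1:20, clusters = 2, factor_sd = 1,
                            loading = 2)),
    seed = 41)
  a <- generate_atlas(design)
  norm <- log_normalize(a$counts)
  genes <- a$truth$module_truth$gene_id
  me <- module_eigengenes(as.matrix(norm[, genes]),
                          setNames(rep(1L, length(genes)), genes))
  res <- permutation_association(me$eigengenes, a$labels,
                                 n_perm = 1000, seed = 7)
  hit <- res[res$cluster == "2", ]
  expect_lte(hit$p_perm, 2 / 1000)
  expect_lt(hit$q_fdr, 0.05)
})

test_that("intramodular connectivity follows its closed forms", {
  v <- rnorm(40)
  X <- cbind(g1 = v, g2 = v)          # perfectly correlated pair: a = 1, K = 2
  rownames(X) <- paste0("c", 1:40)
  expect_equal(module_connectivity(X, beta = 2), 2, tolerance = 1e-10)
  expect_identical(module_connectivity(X, beta = 2),
                   module_connectivity(X, beta = 2))
  ## independent genes: K small and decreasing with n
  set.seed(52)
  K_small <- median(replicate(20, {
    X1 <- matrix(rnorm(30 * 4), 30, dimnames = list(NULL, paste0("g", 1:4)))
    module_connectivity(X1, beta = 2)
  }))
  K_large <- median(replicate(20, {
    X2 <- matrix(rnorm(600 * 4), 600, dimnames = list(NULL, paste0("g", 1:4)))
    module_connectivity(X2, beta = 2)
  }))
  expect_lt(K_large, K_small)
  expect_lt(K_large, 0.5)
  expect_error(module_connectivity(X[1:2, ]), "3 cells")
})

test_that("dropping the driver cluster depresses connectivity detectably", {
  design <- atlas_design(
    n_cells_per_cluster = rep(120, 4), n_genes = 80, baseline_mean = 0.6,
    module_plan = list(list(genes = 1:15, clusters = 3, factor_sd = 1,
                            loading = 2)),
    seed = 43)
  a <- generate_atlas(design)
  norm <- log_normalize(a$counts)
  genes <- a$truth$module_truth$gene_id
  module <- setNames(ifelse(colnames(norm) %in% genes, 1L, 0L),
                     colnames(norm))
  res <- connectivity_drop(as.matrix(norm), module, a$labels, beta = 2,
                           n_perm = 200, seed = 11)
  expect_equal(nrow(res), 4L)
  driver <- res[res$cluster == "3", ]
  others <- res[res$cluster != "3", ]
  expect_equal(driver$delta, max(res$delta))
  expect_lte(driver$p_perm, 0.05)
  expect_gt(min(others$p_perm), 0.05)
  ## determinism
  res2 <- connectivity_drop(as.matrix(norm), module, a$labels, beta = 2,
                            n_perm = 200, seed = 11)
  expect_identical(res, res2)
})

test_that("BH correction matches its hand-computed step-up values", {
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  expect_equal(fdr_correct(0.2), 0.2)
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  expect_equal(fdr_correct(p), p.adjust(p, "BH"))
  expect_error(fdr_correct(c(0.1, NA)), "NA")
  expect_error(fdr_correct(c(0.1, 1.2)), "\\[0, 1\\]")
})
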