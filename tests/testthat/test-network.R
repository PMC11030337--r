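# Network construction: bicor against the loop oracle, soft-threshold
# selection, TOM against the triple-loop oracle, module cutting, eigengenes
# against an SVD oracle, eigengene merging.

test_that("bicor has unit self-correlation and exact antisymmetry", {
  set.seed(1)
  x <- rnorm(30)
  X <- cbind(a = x, b = -x, c = rnorm(30))
  rownames(X) <- paste0("c", 1:30)
  C <- bicor_matrix(X)
  expect_equal(C["a", "a"], 1)
  expect_equal(C["a", "b"], -1, tolerance = 1e-12)
  expect_true(max(abs(C - t(C))) < 1e-12)
})

test_that("vectorized bicor matches the loop transcription", {
  set.seed(2)
  for (k in 1:20) {
    X <- cbind(rnorm(20), rt(20, df = 3))
    rownames(X) <- paste0("c", 1:20)
    colnames(X) <- c("x", "y")
    C <- bicor_matrix(X)
    expect_equal(C["x", "y"], bicor_loop(X[, 1], X[, 2]), tolerance = 1e-10)
  }
})

test_that("zero-MAD genes fall back to Pearson and constants are flagged", {
  set.seed(3)
  x <- rnorm(25)
  spiky <- c(rep(0, 20), 5, 6, 7, 8, 9)     # median-heavy: MAD 0, sd > 0
  X <- cbind(x = x, spiky = spiky, const = rep(2, 25))
  rownames(X) <- paste0("c", 1:25)
  C <- bicor_matrix(X)
  expect_true(attr(C, "fallback")["spiky"])
  expect_true(attr(C, "constant")["const"])
  expect_equal(C["x", "const"], 0)
  expect_equal(C["const", "const"], 1)
  ## hybrid pair agrees with the loop oracle (Pearson side inside)
  expect_equal(C["x", "spiky"], bicor_loop(x, spiky), tolerance = 1e-10)
})

test_that("bicor tracks Pearson on clean bivariate normal samples", {
  set.seed(4)
  n <- 500
  z <- rnorm(n)
  X <- cbind(a = z + rnorm(n, sd = 0.8), b = z + rnorm(n, sd = 0.8))
  rownames(X) <- paste0("c", 1:n)
  C <- bicor_matrix(X)
  expect_equal(C["a", "b"], cor(X[, "a"], X[, "b"]), tolerance = 0.05)
})

test_that("soft-threshold selection honours overrides and flags degeneracy", {
  set.seed(5)
  X <- matrix(rnorm(200 * 40), 200, dimnames = list(NULL, paste0("g", 1:40)))
  C <- cor(X)
  st <- pick_soft_threshold(C, override = 2)
  expect_equal(st$power, 2)
  expect_equal(nrow(st$fit_table), 10L)
  expect_error(pick_soft_threshold(diag(40)), "manual")
})

test_that("scale-free networks fit near 1 at the generating structure", {
  ## power-law degree sequence: correlation c_ij = sqrt(w_i w_j) gives
  ## k_i proportional to w_i at beta = 1
  set.seed(6)
  n <- 400
  w <- (1:n)^(-0.7)
  w <- w / max(w)
  C <- sqrt(outer(w, w))
  diag(C) <- 1
  dimnames(C) <- list(paste0("g", 1:n), paste0("g", 1:n))
  st <- pick_soft_threshold(C, candidate_powers = 1)
  expect_lt(st$fit_table$slope[1], 0)
  expect_gt(st$fit_table$signed_fit[1], 0.8)
})

test_that("TOM matches closed forms and the triple-loop oracle", {
  ## disconnected graph
  A0 <- diag(4)
  expect_equal(tom_similarity(A0), diag(4))
  ## complete graph on 3 genes: TOM = (1 + 1) / (2 + 1 - 1) = 1
  A1 <- matrix(1, 3, 3)
  expect_equal(tom_similarity(A1), matrix(1, 3, 3), ignore_attr = TRUE)
  ## random adjacencies against the oracle
  set.seed(7)
  for (k in 1:5) {
    A <- matrix(runif(30 * 30), 30)
    A <- (A + t(A)) / 2
    diag(A) <- 1
    TOM <- tom_similarity(A)
    expect_equal(TOM, tom_loop(A), tolerance = 1e-12, ignore_attr = TRUE)
    expect_true(all(TOM <= 1 + 1e-12) && all(TOM >= 0))
  }
  expect_error(tom_similarity(matrix(2, 3, 3)), "\\[0, 1\\]")
})

test_that("module cutting recovers planted blocks and rejects noise", {
  ## two perfect 20-gene blocks
  D <- matrix(1, 40, 40)
  D[1:20, 1:20] <- 0
  D[21:40, 21:40] <- 0
  diag(D) <- 0
  dimnames(D) <- list(paste0("g", 1:40), paste0("g", 1:40))
  asg <- cut_modules(D, min_cluster_size = 15)
  expect_equal(sort(unique(asg$module)), c(1L, 2L))
  expect_equal(length(unique(asg$module[1:20])), 1L)
  expect_equal(length(unique(asg$module[21:40])), 1L)
  ## all-independent genes: everything unassigned
  D1 <- matrix(1, 30, 30); diag(D1) <- 0
  dimnames(D1) <- list(paste0("g", 1:30), paste0("g", 1:30))
  expect_true(all(cut_modules(D1, min_cluster_size = 5)$module == 0))
  ## a block below the size floor lands in module 0
  D2 <- matrix(1, 30, 30)
  D2[1:10, 1:10] <- 0
  diag(D2) <- 0
  dimnames(D2) <- list(paste0("g", 1:30), paste0("g", 1:30))
  asg2 <- cut_modules(D2, min_cluster_size = 15)
  expect_true(all(asg2$module == 0))
  ## fewer genes than the floor: warned, all unassigned
  expect_warning(asg3 <- cut_modules(D1[1:5, 1:5], min_cluster_size = 15),
                 "fewer genes")
  expect_true(all(asg3$module == 0))
})

test_that("eigengenes match an independent SVD oracle up to sign", {
  set.seed(8)
  for (k in 1:10) {
    n <- 40; g <- sample(3:8, 1)
    X <- matrix(rnorm(n * g), n) %*% diag(runif(g, 0.5, 2)) +
      outer(rnorm(n), runif(g, 0.5, 1.5))
    dimnames(X) <- list(paste0("c", 1:n), paste0("g", 1:g))
    module <- setNames(rep(1L, g), colnames(X))
    me <- module_eigengenes(X, module)
    e <- me$eigengenes[, 1]
    Z <- scale(X)
    pc <- prcomp(Z, center = FALSE, scale. = FALSE)
    ref <- pc$x[, 1] / sqrt(sum(pc$x[, 1]^2))
    expect_equal(abs(sum(e * ref)), 1, tolerance = 1e-10)
    expect_equal(sqrt(sum(e^2)), 1, tolerance = 1e-12)
    expect_gte(cor(e, rowMeans(Z)), 0)
    expect_equal(me$var_explained[[1]],
                 pc$sdev[1]^2 / sum(pc$sdev^2), tolerance = 1e-10)
  }
})

test_that("a rank-1 module gives a perfectly explained eigengene", {
  v <- rnorm(30)
  X <- cbind(g1 = v, g2 = v, g3 = v)
  rownames(X) <- paste0("c", 1:30)
  me <- module_eigengenes(X, setNames(rep(1L, 3), colnames(X)))
  expect_equal(abs(cor(me$eigengenes[, 1], v)), 1, tolerance = 1e-12)
  expect_gt(cor(me$eigengenes[, 1], v), 0)
  expect_equal(me$var_explained[[1]], 1, tolerance = 1e-12)
})

test_that("eigengene explains at least as much variance as the module mean", {
  set.seed(9)
  X <- matrix(rnorm(50 * 6), 50, dimnames = list(paste0("c", 1:50),
                                                 paste0("g", 1:6)))
  me <- module_eigengenes(X, setNames(rep(1L, 6), colnames(X)))
  Z <- scale(X)
  mvec <- rowMeans(Z)
  mvec <- mvec / sqrt(sum(mvec^2))
  var_mean <- sum((t(Z) %*% mvec)^2) / sum(Z^2)
  expect_gte(me$var_explained[[1]] + 1e-12, var_mean)
})

test_that("correlated module eigengenes merge below the cutoff", {
  set.seed(10)
  n <- 80
  f <- rnorm(n)
  make_block <- function(f, g, noise) {
    sapply(seq_len(g), function(i) f + rnorm(n, sd = noise))
  }
  X <- cbind(make_block(f, 6, 0.3),       # two blocks driven by the same factor
             make_block(f, 6, 0.3),
             make_block(rnorm(n), 6, 0.3))  # independent block
  dimnames(X) <- list(paste0("c", 1:n), paste0("g", 1:18))
  module <- setNames(rep(1:3, each = 6), colnames(X))
  asg <- structure(list(module = module, sizes = rep(6L, 3),
                        cut_height = NA, merge_heights = numeric(),
                        tree = NULL), class = "module_assignment")
  merged <- merge_modules(X, asg, dissim_cutoff = 0.35)
  mod <- merged$assignment$module
  expect_equal(unname(mod[1]), unname(mod[7]))     # shared-factor blocks merged
  expect_false(unname(mod[1]) == unname(mod[13]))  # independent block kept
  expect_equal(length(unique(mod)), 2L)
  ## far-apart eigengenes stay unmerged
  X13 <- X[, c(1:6, 13:18)]
  asg13 <- structure(list(module = setNames(rep(1:2, each = 6), colnames(X13)),
                          sizes = rep(6L, 2), cut_height = NA,
                          merge_heights = numeric(), tree = NULL),
                     class = "module_assignment")
  merged2 <- merge_modules(X13, asg13, dissim_cutoff = 0.35)
  expect_equal(length(unique(merged2$assignment$module)), 2L)
  ## single module passes through unchanged
  asg1 <- structure(list(module = setNames(rep(1L, 6), colnames(X)[1:6]),
                         sizes = 6L, cut_height = NA,
                         merge_heights = numeric(), tree = NULL),
                    class = "module_assignment")
  merged1 <- merge_modules(X[, 1:6], asg1)
  expect_equal(merged1$assignment$module, asg1$module)
})
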