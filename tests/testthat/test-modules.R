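test_that("correlation distance follows 1 - r", {
  x <- c(1, 2, 3)
  expect_equal(correlation_distance(x, x), 0)
  expect_equal(correlation_distance(x, -x), 2)
  expect_equal(correlation_distance(x, c(1, 2, 4)), 0.01801949,
               tolerance = 1e-6)
  expect_error(correlation_distance(x, c(1, 1, 1)), "constant")
  expect_error(correlation_distance(x, 1:4), "equal length")
  expect_error(correlation_distance(1:2, 2:1), "at least 3")
})

test_that("adjusted Rand index agrees with an independent implementation", {
  skip_if_not_installed("mclust")
  withr::with_seed(29, {
    for (i in 1:5) {
      a <- sample(1:4, 60, replace = TRUE)
      b <- sample(letters[1:3], 60, replace = TRUE)
      expect_equal(adjusted_rand_index(a, b),
                   mclust::adjustedRandIndex(a, b), tolerance = 1e-12)
    }
  })
  expect_equal(adjusted_rand_index(rep(1:2, 5), rep(c("x", "y"), 5)), 1)
})

test_that("gene clustering reproduces forced geometries", {
  g1 <- c(1, 2, 3, 4, 2)
  m <- rbind(a = g1, b = g1, c = -g1)
  colnames(m) <- paste0("s", 1:5)
  hc <- cluster_genes(expr_collection(m))
  expect_equal(hc$height[1], 0)                       # identical pair first
  expect_equal(hc$height[2], 2)                       # anti-correlated last
  merged_first <- rownames(m)[-hc$merge[1, ]]
  expect_setequal(merged_first, c("a", "b"))
})

# independent naive O(n^3) complete-linkage oracle returning the cophenetic
# (merge-height) matrix
naive_complete_linkage <- function(d) {
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  active <- rep(TRUE, length(clusters))
  dist_cc <- function(a, b) max(d[clusters[[a]], clusters[[b]]])
  while (sum(active) > 1) {
    idx <- which(active)
    best <- c(NA, NA); bh <- Inf
    for (i in idx) for (j in idx) {
      if (i >= j) next
      h <- dist_cc(i, j)
      if (h < bh) { bh <- h; best <- c(i, j) }
    }
    coph[clusters[[best[1]]], clusters[[best[2]]]] <- bh
    coph[clusters[[best[2]]], clusters[[best[1]]]] <- bh
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    active[best[2]] <- FALSE
  }
  coph
}

test_that("complete-linkage tree matches a naive oracle on 30 genes", {
  m <- toy_matrix(30, 15, seed = 21)
  coll <- expr_collection(m)
  hc <- cluster_genes(coll)
  d <- 1 - cor(t(m))
  expected <- naive_complete_linkage(d)
  got <- as.matrix(stats::cophenetic(hc))
  expect_equal(unname(got[rownames(m), rownames(m)]), unname(expected),
               tolerance = 1e-10)
})

test_that("dynamic cut recovers perfect blocks and enforces module size", {
  withr::with_seed(31, {
    f1 <- rnorm(20)
    f2 <- rnorm(20)
    f2 <- residuals(lm(f2 ~ f1))   # orthogonal blocks by construction
    m <- rbind(t(replicate(6, f1 + rnorm(20, sd = 0.01))),
               t(replicate(6, f2 + rnorm(20, sd = 0.01))))
    dimnames(m) <- list(sprintf("g%02d", 1:12), sprintf("s%02d", 1:20))
  })
  coll <- expr_collection(m)
  ms <- dynamic_cut(cluster_genes(coll), min_module_size = 5, coll = coll)
  expect_length(ms$modules, 2)
  expect_setequal(ms$modules$M1, sprintf("g%02d", 1:6))
  expect_setequal(ms$modules$M2, sprintf("g%02d", 7:12))
  expect_true(all(lengths(ms$modules) >= 5))
  expect_error(dynamic_cut(cluster_genes(coll), min_module_size = 1),
               "min_module_size")
})

test_that("i.i.d. noise genes stay mostly unassigned", {
  frac <- vapply(1:20, function(s) {
    m <- withr::with_seed(100 + s, {
      mm <- matrix(rnorm(20 * 30), 20, 30)
      dimnames(mm) <- list(sprintf("g%02d", 1:20), sprintf("s%02d", 1:30))
      mm
    })
    coll <- expr_collection(m)
    ms <- dynamic_cut(cluster_genes(coll), min_module_size = 5, coll = coll)
    length(ms$unassigned) / 20
  }, 0)
  expect_gte(mean(frac), 0.6)
})

test_that("module discovery is invariant to sample and gene permutation", {
  sim <- quick_sim(seed = 6)
  coll <- median_center_by_dataset(sim$expression)
  base <- discover_modules(coll)
  withr::with_seed(41, {
    sp <- sample(ncol(coll$values))
    gp <- sample(nrow(coll$values))
  })
  perm <- expr_collection(coll$values[gp, sp], coll$dataset[sp],
                          allow_missing = TRUE)
  other <- discover_modules(perm)
  a <- recovered_partition(base)
  b <- recovered_partition(other)
  common <- intersect(names(a), names(b))
  expect_gte(length(common) / length(a), 0.98)
  expect_equal(adjusted_rand_index(a[common], b[common]), 1)
})

test_that("robustness screen discards one-dataset-only and excluded modules", {
  # module A correlated in both datasets; module B correlated only in D1
  withr::with_seed(51, {
    n1 <- 40; n2 <- 40
    fA1 <- rnorm(n1); fA2 <- rnorm(n2); fB1 <- rnorm(n1)
    mkblock <- function(f, k, sd) t(replicate(k, f + rnorm(length(f), sd = sd)))
    d1 <- rbind(mkblock(fA1, 5, 0.3), mkblock(fB1, 5, 0.3))
    d2 <- rbind(mkblock(fA2, 5, 0.3),
                matrix(rnorm(5 * n2), 5))         # B is noise in D2
    m <- cbind(d1, d2)
    dimnames(m) <- list(c(sprintf("a%d", 1:5), sprintf("b%d", 1:5)),
                        sprintf("s%02d", 1:(n1 + n2)))
  })
  coll <- expr_collection(m, dataset = rep(c("D1", "D2"), c(40, 40)))
  ms <- gene_module_set(list(A = sprintf("a%d", 1:5), B = sprintf("b%d", 1:5)))
  out <- module_robustness(ms, coll, r_min = 0.5)
  expect_true(out$robust[["A"]])
  expect_false(out$robust[["B"]])
  expect_equal(out$discarded[["B"]], "non-robust")

  out2 <- module_robustness(ms, coll, exclude_genes = "a3")
  expect_equal(out2$discarded[["A"]], "excluded-genes")

  bad <- gene_module_set(list(A = c("a1", "zz")))
  expect_error(module_robustness(bad, coll), "unknown gene")
})

test_that("module recovery is stable under 90% sample subsampling", {
  sim <- quick_sim(seed = 8)
  coll <- median_center_by_dataset(sim$expression)
  n <- ncol(coll$values)
  parts <- lapply(1:10, function(i) {
    idx <- withr::with_seed(200 + i, sample(n, round(0.9 * n)))
    recovered_partition(discover_modules(coll[, idx]))
  })
  aris <- combn(10, 2, function(ij) {
    a <- parts[[ij[1]]]; b <- parts[[ij[2]]]
    common <- intersect(names(a), names(b))
    adjusted_rand_index(a[common], b[common])
  })
  expect_gte(mean(aris), 0.6)
})
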