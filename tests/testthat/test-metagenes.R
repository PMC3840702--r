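test_that("meta-genes are module medians", {
  m <- toy_matrix(7, 9)
  coll <- expr_collection(m)
  ms <- gene_module_set(list(M1 = rownames(m)[1],
                             M2 = rownames(m)[2:4],
                             M3 = rownames(m)[5:7]))
  mg <- compute_metagenes(coll, ms, center_rows = FALSE)
  expect_equal(mg$values["M1", ], m[1, ])                 # singleton identity
  expect_equal(unname(mg$values["M2", 1]), median(m[2:4, 1]))
  # brute force: sort and take middle / mean of middle two
  g6 <- m[2:4, 5]
  expect_equal(unname(mg$values["M2", 5]), unname(sort(g6)[2]))
  even <- apply(m[c(2, 3, 5, 7), , drop = FALSE], 2, function(v)
    mean(sort(v)[2:3]))
  mg2 <- compute_metagenes(coll, gene_module_set(
    list(E = rownames(m)[c(2, 3, 5, 7)])), center_rows = FALSE)
  expect_equal(unname(mg2$values["E", ]), unname(even))

  expect_error(compute_metagenes(coll, gene_module_set(list(M = "nope"))),
               "absent")
})

test_that("simple numeric median check {1,2,3} -> 2", {
  m <- matrix(c(1, 2, 3), 3, 1, dimnames = list(c("a", "b", "c"), "s1"))
  coll <- expr_collection(m)
  mg <- compute_metagenes(coll, gene_module_set(list(M = c("a", "b", "c"))),
                          center_rows = FALSE)
  expect_equal(unname(mg$values["M", "s1"]), 2)
})

test_that("meta-gene clustering groups duplicates and leaves noise ungrouped", {
  sim <- quick_sim(seed = 13)
  coll <- median_center_by_dataset(sim$expression)
  mg <- compute_metagenes(coll, gene_module_set(sim$true_modules))
  # duplicate two meta-gene rows: they must share a cluster
  v <- rbind(mg$values, dup1 = mg$values[1, ], dup2 = mg$values[1, ])
  mg2 <- mg; mg2$values <- v
  cl <- cluster_metagenes(mg2, n_clusters = 4)
  expect_equal(as.character(cl["dup1"]), as.character(cl["dup2"]))
  expect_equal(as.character(cl["dup1"]), as.character(cl[rownames(mg$values)[1]]))
})

test_that("planted meta-gene factor groups are recovered", {
  withr::with_seed(61, {
    n <- 50
    fac <- replicate(3, rnorm(n))
    rows <- do.call(rbind, lapply(1:3, function(g)
      t(replicate(4, fac[, g] + rnorm(n, sd = 0.3)))))
    dimnames(rows) <- list(sprintf("mg%02d", 1:12), sprintf("s%02d", 1:n))
  })
  mg <- structure(list(values = rows,
                       module_genes = setNames(as.list(rownames(rows)),
                                               rownames(rows)),
                       dataset = factor(rep("D1", 50))),
                  class = "metagene_matrix")
  cl <- cluster_metagenes(mg, n_clusters = 3)
  truth <- rep(1:3, each = 4)
  expect_gte(adjusted_rand_index(as.character(cl), truth), 0.9)
})

test_that("consensus distance has pseudo-metric structure and exact extremes", {
  sim <- quick_sim(seed = 14)
  coll <- median_center_by_dataset(sim$expression)
  mg <- compute_metagenes(coll, gene_module_set(sim$true_modules))
  # duplicate a sample: distance 0 whenever co-sampled
  v <- cbind(mg$values, dup = mg$values[, 1])
  mg2 <- mg
  mg2$values <- v
  mg2$dataset <- factor(c(as.character(mg$dataset), "D1"))
  cm <- consensus_matrix(mg2, n_resamples = 50, subsample_frac = 0.8,
                         k_base = 3, seed = 2)
  expect_equal(cm$distance[colnames(mg$values)[1], "dup"], 0)
  expect_true(isSymmetric(cm$distance))
  expect_equal(unname(diag(cm$distance)), rep(0, ncol(v)))
  expect_true(all(cm$distance >= 0 & cm$distance <= 1))

  # subsample_frac 1, one resample: 0/1 indicator of the base partition
  cm1 <- consensus_matrix(mg, n_resamples = 1, subsample_frac = 1,
                          k_base = 3, seed = 5)
  expect_true(all(cm1$distance %in% c(0, 1)))
})

test_that("consensus matrix equals a brute-force co-clustering oracle", {
  sim <- quick_sim(seed = 15)
  coll <- median_center_by_dataset(sim$expression)
  mg <- compute_metagenes(coll, gene_module_set(sim$true_modules))
  mg$values <- mg$values[, 1:40]
  mg$dataset <- mg$dataset[1:40]
  got <- consensus_matrix(mg, n_resamples = 10, subsample_frac = 0.8,
                          k_base = 3, seed = 77)

  # independent re-run: record every co-clustering event explicitly
  x <- mg$values
  n <- 40; m <- floor(0.8 * n)
  co <- matrix(0, n, n); pc <- matrix(0, n, n)
  withr::with_seed(77, {
    for (r in 1:10) {
      idx <- sort(sample.int(n, m))
      cl <- cutree(hclust(as.dist(1 - cor(x[, idx])), method = "complete"),
                   k = 3)
      for (i in seq_along(idx)) for (j in seq_along(idx)) {
        pc[idx[i], idx[j]] <- pc[idx[i], idx[j]] + 1
        if (cl[i] == cl[j]) co[idx[i], idx[j]] <- co[idx[i], idx[j]] + 1
      }
    }
  })
  expected <- 1 - co / pc
  expected[pc == 0] <- 1
  diag(expected) <- 0
  expect_identical(unname(got$distance), expected)
})

test_that("pruning yields subtypes on core samples and flags outliers", {
  # degenerate: all samples identical in consensus (distance 0)
  d0 <- matrix(0, 20, 20, dimnames = list(paste0("s", 1:20), paste0("s", 1:20)))
  cm <- structure(list(distance = d0, pair_counts = matrix(10, 20, 20),
                       n_resamples = 10), class = "consensus_matrix")
  a <- define_subtypes(cm, min_subtype_size = 5)
  expect_equal(nlevels(a$subtype), 1)
  expect_true(all(a$core))

  # one far outlier: never co-clusters with anyone
  d1 <- d0; d1[20, -20] <- 1; d1[-20, 20] <- 1
  cm1 <- structure(list(distance = d1, pair_counts = matrix(10, 20, 20),
                        n_resamples = 10), class = "consensus_matrix")
  a1 <- define_subtypes(cm1, min_subtype_size = 5)
  expect_false(a1$core[20])
  expect_true(all(a1$core[1:19]))

  # no admissible cluster -> all non-core with a warning
  expect_warning(a2 <- define_subtypes(cm1, min_subtype_size = 21),
                 "no cluster")
  expect_true(all(!a2$core))
})

test_that("raising the prune height never shrinks the core", {
  sim <- quick_sim(seed = 16)
  coll <- median_center_by_dataset(sim$expression)
  mg <- compute_metagenes(coll, gene_module_set(sim$true_modules))
  cm <- consensus_matrix(mg, n_resamples = 100, k_base = 3, seed = 3)
  cores <- vapply(c(0.15, 0.35, 0.6),
                  function(h) sum(define_subtypes(cm, prune_height = h,
                                                  min_subtype_size = 5)$core),
                  0)
  expect_true(all(diff(cores) >= 0))
})
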