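test_that("BH adjustment reproduces hand-computed step-up values", {
  expect_equal(bh_adjust(0.4), 0.4)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.7, 0.01, 0.3)
  expect_true(all(bh_adjust(p) >= p))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("sign test gives exact binomial p-values", {
  expect_equal(sign_test(rep(1, 5))$p.value, 0.0625)
  expect_equal(sign_test(c(1, 1, -1, -1))$p.value, 1)
  expect_equal(sign_test(c(rep(1, 7), rep(-1, 3)))$p.value, 0.34375)
  expect_equal(sign_test(c(1, 0, 0, -1, 1))$n, 3)   # zeros dropped
  expect_error(sign_test(c(0, 0)), "all differences")
})

test_that("Fisher enrichment matches the exact hypergeometric value", {
  # group of 4 with 3 positives vs rest of 4 with 1 positive: p = 34/70
  labels <- subtype_assignment(paste0("s", 1:8),
                               rep(c("S1", "S2"), each = 4))
  marker <- setNames(c(1, 1, 1, 0, 1, 0, 0, 0), paste0("s", 1:8))
  res <- enrichment_test(labels, marker)
  expect_equal(res$p[res$group == "S1"], 34 / 70, tolerance = 1e-12)

  # a subtype with the population proportion: OR 1, p 1
  labels2 <- subtype_assignment(paste0("s", 1:8),
                                rep(c("A", "B"), each = 4))
  marker2 <- setNames(rep(c(1, 0), 4), paste0("s", 1:8))
  res2 <- enrichment_test(labels2, marker2)
  expect_equal(res2$odds_ratio, c(1, 1))
  expect_equal(res2$p, c(1, 1))

  expect_error(enrichment_test(labels, setNames(rep(1, 8), paste0("s", 1:8))),
               "both values")
})

test_that("enrichment p-values are calibrated under independence", {
  # null: marker independent of subtype; one p per simulation. Groups are
  # sized so the exact test's discrete support is dense enough for the
  # uniformity check to be meaningful.
  pvals <- vapply(1:200, function(s) {
    withr::with_seed(3000 + s, {
      lab <- subtype_assignment(paste0("s", 1:600),
                                sample(rep(c("S1", "S2", "S3"), each = 200)))
      mk <- setNames(rbinom(600, 1, 0.3), paste0("s", 1:600))
    })
    enrichment_test(lab, mk)$p[1]
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
  # type-I error no worse than 1.5x nominal
  expect_lte(mean(pvals < 0.05), 1.5 * 0.05 + 2 * sqrt(0.05 * 0.95 / 200))
})

test_that("differential meta-gene expression flags planted shifts only", {
  withr::with_seed(101, {
    v <- matrix(rnorm(10 * 100, sd = 0.5), 10)
    dimnames(v) <- list(sprintf("M%d", 1:10), sprintf("s%03d", 1:100))
    v[1, 1:50] <- v[1, 1:50] + 1   # shift of 2*noise_sd on one meta-gene
  })
  mg <- structure(list(values = v, module_genes = list(),
                       dataset = factor(rep("D1", 100))),
                  class = "metagene_matrix")
  labels <- subtype_assignment(colnames(v), rep(c("S1", "S2"), each = 50))
  res <- diff_metagene_expression(mg, labels)
  expect_lt(res$p_adj[res$metagene == "M1"], 0.01)
  expect_true(all(res$p_adj >= res$p))

  # identical groups: t ~ 0, adjusted p ~ 1
  v2 <- v; v2[, 51:100] <- v2[, 1:50]
  mg2 <- mg; mg2$values <- v2
  res2 <- diff_metagene_expression(mg2, labels)
  expect_equal(res2$t, rep(0, 10), tolerance = 1e-12)
  expect_equal(res2$p_adj, rep(1, 10), tolerance = 1e-12)
})

test_that("GSEA running sum has the extremal and symmetry properties", {
  withr::with_seed(102, {
    v <- matrix(rnorm(60 * 30), 60,
                dimnames = list(sprintf("g%02d", 1:60),
                                sprintf("s%02d", 1:30)))
  })
  coll <- expr_collection(v)
  labels <- subtype_assignment(colnames(v), rep(c("A", "B"), each = 15))
  metric <- crcmods:::subtype_ranking_metric(coll, labels, "A")

  topk <- names(sort(metric, decreasing = TRUE))[1:8]
  s_top <- crcmods:::ks_running_score(metric, topk)
  expect_equal(s_top, 1)   # maximal achievable deviation
  withr::with_seed(103, {
    for (i in 1:20) {
      s <- crcmods:::ks_running_score(metric, sample(names(metric), 8))
      expect_lte(abs(s), 1)
      expect_lte(s, s_top)
    }
  })

  # rank reversal (negated metric) flips the sign, keeps the magnitude
  set <- sample(names(metric), 10)
  expect_equal(crcmods:::ks_running_score(-metric, set),
               -crcmods:::ks_running_score(metric, set), tolerance = 1e-12)
})

test_that("GSEA permutation p-values are uniform for random sets", {
  sim <- quick_sim(seed = 23)
  coll <- median_center_by_dataset(sim$expression)
  labels <- truth_assignment(sim)
  genes <- rownames(coll$values)
  pvals <- vapply(1:200, function(i) {
    set <- withr::with_seed(4000 + i, sample(genes, 15))
    gsea_score(coll, labels, set, "S1", n_perm = 200, seed = i)$p
  }, 0)
  expect_gt(suppressWarnings(ks.test(pvals, "punif"))$p.value, 0.01)
})

test_that("gsea_score flags planted sets and validates input", {
  sim <- quick_sim(seed = 24)
  coll <- median_center_by_dataset(sim$expression)
  labels <- truth_assignment(sim)
  # a module shifted up in S1 per the planted pattern
  shifted <- names(which(sim$shift_pattern["S1", ] != 0))[1]
  sgn <- sign(sim$shift_pattern["S1", shifted])
  gs <- gsea_score(coll, labels, sim$true_modules[[shifted]], "S1",
                   n_perm = 500, seed = 9)
  expect_lt(gs$p, 0.05)
  expect_equal(gs$sign, unname(sgn))
  expect_error(gsea_score(coll, labels, c("g0001", "g0002"), "S1"),
               "< 3 genes")
})

test_that("aggregation averages member scores per motif", {
  sc <- function(score, subtype)
    structure(list(score = score, p = NA, sign = sign(score),
                   n_genes = 5, subtype = subtype), class = "gsea_score")
  one <- aggregate_enrichment(list(sc(0.4, "A")))
  expect_equal(one$score, 0.4)
  zero <- aggregate_enrichment(list(sc(0.5, "A"), sc(-0.5, "A")))
  expect_equal(zero$score, 0)
  three <- aggregate_enrichment(list(sc(0.2, "A"), sc(0.4, "A"),
                                     sc(0.9, "A")))
  expect_equal(three$score, 0.5)
  expect_equal(three$n_sets, 3)
})
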