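#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with running-minimum enforcement,
#' preserving input order. Delegates to [stats::p.adjust] after validating
#' the input.
#'
#' @param pvalues numeric vector of p-values in `[0, 1]` (`NA` allowed and
#'   propagated).
#' @return The BH-adjusted vector, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  ok <- is.na(pvalues) | (pvalues >= 0 & pvalues <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Exact sign test for paired differences
#'
#' Two-sided exact binomial test of the number of positive differences
#' against Binomial(n, 1/2); zero differences are dropped.
#'
#' @param x numeric vector of paired differences.
#' @return List with `n` (nonzero differences), `n_positive` and `p.value`.
#' @export
sign_test <- function(x) {
  x <- x[!is.na(x)]
  x <- x[x != 0]
  if (!length(x)) stop("all differences are zero")
  np <- sum(x > 0)
  list(n = length(x), n_positive = np,
       p.value = stats::binom.test(np, length(x), 0.5)$p.value)
}

#' Differential meta-gene expression between subtypes
#'
#' All pairwise subtype contrasts per meta-gene, using the moderated-t
#' machinery (prior estimated across meta-genes per contrast), with BH
#' adjustment across the full (meta-gene x contrast) grid.
#'
#' @param mg a `metagene_matrix`.
#' @param labels a `subtype_assignment` with >= 2 subtypes of >= 3 core
#'   samples.
#' @return A data.frame: `metagene`, `group1`, `group2`, `diff`, `t`, `p`,
#'   `p_adj`.
#' @export
diff_metagene_expression <- function(mg, labels) {
  stopifnot(inherits(mg, "metagene_matrix"),
            inherits(labels, "subtype_assignment"))
  lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  lab <- lab[labels$core & !is.na(lab)]
  common <- intersect(names(lab), colnames(mg$values))
  lab <- lab[common]
  subs <- names(which(table(lab) >= 3))
  if (length(subs) < 2)
    stop("need >= 2 subtypes with >= 3 core samples")
  out <- list()
  for (i in seq_along(subs)) for (j in seq_along(subs)) {
    if (i >= j) next
    x1 <- mg$values[, common[lab == subs[i]], drop = FALSE]
    x2 <- mg$values[, common[lab == subs[j]], drop = FALSE]
    mt <- moderated_t_two_group(x1, x2)
    out[[length(out) + 1L]] <- data.frame(
      metagene = rownames(mg$values), group1 = subs[i], group2 = subs[j],
      diff = mt$diff, t = mt$t, p = mt$p, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Marker enrichment of subtypes against the population baseline
#'
#' For each subtype (and the pooled non-core group) and each binary marker,
#' tests whether the marker proportion in the group differs from the
#' baseline, defined as the marker proportion among all samples with
#' available data. The default test is the two-sided Fisher exact test of
#' the group-versus-rest 2x2 table; `binomial_baseline = TRUE` instead
#' tests the group count against the fixed baseline proportion
#' (exact binomial). BH adjustment runs across the whole
#' (group x marker) grid.
#'
#' @param labels a `subtype_assignment`.
#' @param markers a data.frame of 0/1 markers with a `sample_id` column (or
#'   rownames), or a single named 0/1 vector.
#' @param binomial_baseline use the exact binomial test against the fixed
#'   baseline proportion instead of Fisher's group-versus-rest test.
#' @param include_noncore test non-core samples as one group (default TRUE).
#' @return A data.frame: `group`, `marker`, `n_group`, `k_group`,
#'   `baseline`, `proportion`, `odds_ratio`, `direction`
#'   (enriched/depleted/none), `p`, `p_adj`, `testable`.
#' @export
enrichment_test <- function(labels, markers, binomial_baseline = FALSE,
                            include_noncore = TRUE) {
  stopifnot(inherits(labels, "subtype_assignment"))
  if (is.atomic(markers))
    markers <- data.frame(sample_id = names(markers), marker = markers,
                          stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(markers))
    markers <- data.frame(sample_id = rownames(markers), markers,
                          stringsAsFactors = FALSE)
  grp <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  grp[!labels$core] <- "noncore"
  groups <- levels(labels$subtype)
  if (include_noncore && any(!labels$core)) groups <- c(groups, "noncore")

  out <- list()
  for (mk in setdiff(names(markers), "sample_id")) {
    v <- stats::setNames(markers[[mk]], markers$sample_id)
    v <- v[names(grp)]
    avail <- !is.na(v)
    if (!any(avail)) next
    if (length(unique(v[avail])) < 2)
      stop("marker ", mk, " must have both values present")
    baseline <- mean(v[avail])
    n_avail <- sum(avail)
    k_avail <- sum(v[avail])
    for (g in groups) {
      ing <- avail & grp == g & !is.na(grp)
      n_g <- sum(ing); k_g <- sum(v[ing])
      if (n_g == 0) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, marker = mk, n_group = 0L, k_group = 0L,
          baseline = baseline, proportion = NA_real_,
          odds_ratio = NA_real_, direction = "none", p = NA_real_,
          testable = FALSE, stringsAsFactors = FALSE)
        next
      }
      prop <- k_g / n_g
      if (binomial_baseline) {
        p <- stats::binom.test(k_g, n_g, baseline)$p.value
        or <- (prop / (1 - prop)) / (baseline / (1 - baseline))
      } else {
        tab <- matrix(c(k_g, n_g - k_g,
                        k_avail - k_g, n_avail - n_g - (k_avail - k_g)), 2)
        p <- stats::fisher.test(tab)$p.value
        or <- (tab[1, 1] * tab[2, 2]) / (tab[2, 1] * tab[1, 2])
      }
      direction <- if (prop > baseline) "enriched"
                   else if (prop < baseline) "depleted" else "none"
      out[[length(out) + 1L]] <- data.frame(
        group = g, marker = mk, n_group = n_g, k_group = k_g,
        baseline = baseline, proportion = prop, odds_ratio = or,
        direction = direction, p = p, testable = TRUE,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res
}

#' Gene set enrichment score for a subtype
#'
#' Genes are median-centred across all samples, ranked by their average
#' (centred) expression within the subtype, and scored with a weighted
#' Kolmogorov-Smirnov running sum (weight exponent 1 on the ranking
#' metric). The p-value comes from a gene-label permutation null: random
#' gene sets of the same size. Positive scores indicate enrichment among
#' the subtype's up-regulated genes, negative among the down-regulated.
#'
#' @param coll an [expr_collection].
#' @param labels a `subtype_assignment`.
#' @param gene_set character vector of gene ids (intersection with the
#'   collection must have >= 3 genes).
#' @param subtype subtype whose ranking is scored.
#' @param n_perm number of permutations (default 1000).
#' @param seed integer seed.
#' @return A `gsea_score` list: `score`, `p`, `sign`, `n_genes` (set size
#'   used), `subtype`.
#' @export
gsea_score <- function(coll, labels, gene_set, subtype, n_perm = 1000,
                       seed = 1) {
  stopifnot(inherits(coll, "expr_collection"))
  metric <- subtype_ranking_metric(coll, labels, subtype)
  set <- intersect(gene_set, names(metric))
  if (length(set) < 3) stop("gene set has < 3 genes in the collection")
  ord <- order(metric, decreasing = TRUE)
  ranked <- metric[ord]
  obs <- ks_running_score(ranked, set, presorted = TRUE)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(i)
      ks_running_score(ranked, sample(names(ranked), length(set)),
                       presorted = TRUE),
      0)
  })
  p <- (1 + sum(abs(perm) >= abs(obs))) / (1 + n_perm)
  structure(list(score = obs, p = p, sign = sign(obs),
                 n_genes = length(set), subtype = subtype),
            class = "gsea_score")
}

# Average median-centred expression within the subtype, per gene.
subtype_ranking_metric <- function(coll, labels, subtype) {
  stopifnot(inherits(labels, "subtype_assignment"))
  lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  lab <- lab[labels$core & !is.na(lab)]
  ids <- intersect(names(lab)[lab == subtype], colnames(coll$values))
  if (!length(ids)) stop("unknown or empty subtype: ", subtype)
  centred <- coll$values - apply(coll$values, 1, stats::median)
  rowMeans(centred[, ids, drop = FALSE])
}

# Weighted KS running-sum enrichment score (weight exponent 1);
# returns the signed maximal deviation.
ks_running_score <- function(metric, set, presorted = FALSE) {
  ranked <- if (presorted) metric else metric[order(metric, decreasing = TRUE)]
  inset <- names(ranked) %in% set
  w <- abs(ranked)
  denom_hit <- sum(w[inset])
  if (denom_hit == 0) return(0)
  n_miss <- length(ranked) - sum(inset)
  step <- ifelse(inset, w / denom_hit, -1 / n_miss)
  s <- cumsum(step)
  s[which.max(abs(s))]
}

#' Aggregate gene set enrichment scores into motif scores
#'
#' Arithmetic mean of member scores per (motif, subtype) — the convention
#' for composing module-level scores into biological-motif fingerprints.
#'
#' @param scores a data.frame with columns `motif`, `subtype`, `score`, or
#'   a list of `gsea_score` objects plus a `motif` vector.
#' @param motif motif label per score (when `scores` is a list).
#' @return A data.frame: `motif`, `subtype`, `score` (mean), `n_sets`.
#' @export
aggregate_enrichment <- function(scores, motif = NULL) {
  if (!is.data.frame(scores)) {
    stopifnot(length(scores) >= 1)
    scores <- data.frame(
      motif = if (is.null(motif)) "motif" else motif,
      subtype = vapply(scores, function(s) s$subtype, ""),
      score = vapply(scores, function(s) s$score, 0),
      stringsAsFactors = FALSE)
  }
  stopifnot(nrow(scores) >= 1)
  agg <- stats::aggregate(score ~ motif + subtype, scores, mean)
  cnt <- stats::aggregate(score ~ motif + subtype, scores, length)
  agg$n_sets <- cnt$score
  agg
}
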