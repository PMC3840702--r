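#' Reduce samples to meta-genes (module medians)
#'
#' Entry (m, s) is the median expression over module m's genes in sample s.
#'
#' @param coll an [expr_collection] containing every module gene.
#' @param modules a `gene_module_set`; only robust (or unscreened) modules
#'   are used.
#' @param center_rows if `TRUE` (default) each meta-gene is centred to median
#'   zero across samples, the convention used for sample clustering and
#'   classification.
#' @return A `metagene_matrix`: list with `values` (meta-gene x sample
#'   matrix), `module_genes` (named list) and `dataset` (factor per sample).
#' @export
compute_metagenes <- function(coll, modules, center_rows = TRUE) {
  stopifnot(inherits(coll, "expr_collection"))
  if (inherits(modules, "gene_module_set"))
    modules <- robust_modules(modules)$modules
  if (!length(modules)) stop("no modules to summarize")
  if (any(lengths(modules) == 0)) stop("empty module")
  unknown <- setdiff(unlist(modules), rownames(coll$values))
  if (length(unknown))
    stop("module gene(s) absent from collection: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  v <- t(vapply(modules,
                function(g) apply(coll$values[g, , drop = FALSE], 2,
                                  stats::median),
                numeric(ncol(coll$values))))
  dimnames(v) <- list(names(modules), colnames(coll$values))
  if (center_rows) v <- v - apply(v, 1, stats::median)
  structure(list(values = v, module_genes = modules,
                 dataset = coll$dataset),
            class = "metagene_matrix")
}

#' @export
print.metagene_matrix <- function(x, ...) {
  cat(sprintf("metagene_matrix: %d meta-genes x %d samples\n",
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Group meta-genes into module clusters
#'
#' Complete-linkage clustering of meta-gene rows on correlation distance,
#' cut either to a requested number of clusters or by the same static
#' height rule as the gene-level cut. Clusters smaller than
#' `min_cluster_size` are dissolved: their meta-genes stay ungrouped (`NA`).
#'
#' @param mg a `metagene_matrix`.
#' @param n_clusters number of clusters to cut to; if `NULL` the tree is cut
#'   at `cut_height` instead.
#' @param min_cluster_size smallest cluster retained (default 2; singletons
#'   stay ungrouped).
#' @param cut_height cut height used when `n_clusters` is `NULL`.
#' @return A named factor meta-gene -> cluster id (`MC1...`, `NA` for
#'   ungrouped), ids ordered by decreasing cluster size.
#' @export
cluster_metagenes <- function(mg, n_clusters = NULL, min_cluster_size = 2,
                              cut_height = 0.7) {
  stopifnot(inherits(mg, "metagene_matrix"))
  if (!is.null(n_clusters) && n_clusters < 1)
    stop("n_clusters must be >= 1")
  hc <- stats::hclust(stats::as.dist(cor_dist_matrix(mg$values)),
                      method = "complete")
  cl <- if (is.null(n_clusters)) stats::cutree(hc, h = cut_height)
        else stats::cutree(hc, k = min(n_clusters, nrow(mg$values)))
  sizes <- table(cl)
  keep <- names(sizes)[sizes >= min_cluster_size]
  keep <- keep[order(-sizes[keep], as.integer(keep))]
  out <- rep(NA_character_, length(cl))
  names(out) <- names(cl)
  for (i in seq_along(keep))
    out[cl == as.integer(keep[i])] <- sprintf("MC%d", i)
  factor(out)
}

#' Consensus distance over samples by resampled clustering
#'
#' Repeatedly subsamples the samples, clusters each subsample
#' (complete linkage on Pearson correlation distance between sample
#' meta-gene profiles, cut to `k_base` clusters) and records co-clustering:
#' `distance(i, j) = 1 - (#co-clustered) / (#co-sampled)`.
#'
#' @param mg a `metagene_matrix` (rows already median-centred by
#'   [compute_metagenes()]).
#' @param n_resamples number of subsampling rounds (>= 1).
#' @param subsample_frac fraction of samples drawn per round (0, 1].
#' @param k_base number of clusters in each base clustering (>= 2),
#'   normally the intended subtype count.
#' @param seed integer seed.
#' @return A `consensus_matrix`: list with `distance` (sample x sample,
#'   symmetric, zero diagonal, entries in `[0, 1]`), `pair_counts` (times
#'   both members of a pair were sampled) and `n_resamples`.
#' @export
consensus_matrix <- function(mg, n_resamples = 500, subsample_frac = 0.8,
                             k_base = 5, seed = 1) {
  stopifnot(inherits(mg, "metagene_matrix"))
  if (n_resamples < 1) stop("n_resamples must be >= 1")
  if (subsample_frac <= 0 || subsample_frac > 1)
    stop("subsample_frac must be in (0, 1]")
  if (k_base < 2) stop("k_base must be >= 2")
  x <- mg$values
  n <- ncol(x)
  m <- max(2L, floor(subsample_frac * n))
  co <- matrix(0, n, n, dimnames = list(colnames(x), colnames(x)))
  pc <- matrix(0, n, n, dimnames = dimnames(co))
  with_seed(seed, {
    for (r in seq_len(n_resamples)) {
      idx <- sort(sample.int(n, m))
      d <- stats::as.dist(1 - stats::cor(x[, idx, drop = FALSE]))
      cl <- stats::cutree(stats::hclust(d, method = "complete"),
                          k = min(k_base, m))
      pc[idx, idx] <- pc[idx, idx] + 1
      co[idx, idx] <- co[idx, idx] + outer(cl, cl, "==")
    }
  })
  never <- diag(pc) == 0
  if (any(never))
    stop("sample(s) never drawn (", paste(utils::head(colnames(x)[never], 3),
                                          collapse = ", "),
         "); increase n_resamples")
  dist <- 1 - co / pc
  if (any(pc[upper.tri(pc)] == 0)) {
    warning("some sample pairs were never co-sampled; their distance is 1")
    dist[pc == 0] <- 1
  }
  diag(dist) <- 0
  structure(list(distance = dist, pair_counts = pc,
                 n_resamples = n_resamples),
            class = "consensus_matrix")
}

#' @export
print.consensus_matrix <- function(x, ...) {
  cat(sprintf("consensus_matrix: %d samples, %d resamples\n",
              nrow(x$distance), x$n_resamples))
  invisible(x)
}

#' Define subtypes on core samples by dendrogram pruning
#'
#' Average-linkage tree on the consensus distance, cut at `prune_height`;
#' clusters of at least `min_subtype_size` samples become subtypes, labelled
#' `S1, S2, ...` by decreasing size. All remaining samples are non-core.
#' Average linkage is used on the consensus pseudo-metric because its merge
#' heights average out the binomial noise of individual consensus entries;
#' samples that co-cluster consistently sit near height 0 while ambiguous
#' samples sit above ~0.4, which is what the default prune height of 0.2
#' separates (calibration in the package vignette).
#'
#' @param cm a `consensus_matrix`.
#' @param prune_height cut height on the consensus-distance dendrogram,
#'   in (0, 1); default 0.2.
#' @param min_subtype_size smallest admissible subtype; default
#'   `max(10, 3%` of samples`)`.
#' @param linkage linkage for the outer tree on the consensus distance.
#' @return A `subtype_assignment`: data.frame with `sample_id`, `subtype`
#'   (factor, `NA` for non-core) and `core` (logical), plus a `sizes`
#'   attribute.
#' @export
define_subtypes <- function(cm, prune_height = 0.2, min_subtype_size = NULL,
                            linkage = c("average", "complete")) {
  stopifnot(inherits(cm, "consensus_matrix"))
  linkage <- match.arg(linkage)
  if (prune_height <= 0 || prune_height >= 1)
    stop("prune_height must be in (0, 1)")
  n <- nrow(cm$distance)
  if (is.null(min_subtype_size))
    min_subtype_size <- max(10, ceiling(0.03 * n))
  if (min_subtype_size < 2) stop("min_subtype_size must be >= 2")
  hc <- stats::hclust(stats::as.dist(cm$distance), method = linkage)
  cl <- stats::cutree(hc, h = prune_height)
  sizes <- table(cl)
  pass <- names(sizes)[sizes >= min_subtype_size]
  if (!length(pass))
    warning("no cluster passes the minimal size criterion; all samples non-core")
  # decreasing size; ties by first sample index for determinism
  first_idx <- vapply(pass, function(p) min(which(cl == as.integer(p))), 0L)
  pass <- pass[order(-sizes[pass], first_idx)]
  subtype <- rep(NA_character_, n)
  for (i in seq_along(pass))
    subtype[cl == as.integer(pass[i])] <- sprintf("S%d", i)
  out <- data.frame(sample_id = rownames(cm$distance),
                    subtype = factor(subtype,
                                     levels = sprintf("S%d",
                                                      seq_along(pass))),
                    core = !is.na(subtype),
                    stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(out$subtype)
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

#' @export
print.subtype_assignment <- function(x, ...) {
  cat(sprintf("subtype_assignment: %d samples, %d core (%.1f%%)\n",
              nrow(x), sum(x$core), 100 * mean(x$core)))
  if (nlevels(x$subtype) > 0) print(attr(x, "sizes"))
  invisible(x)
}

#' Construct a subtype assignment
#'
#' Builds the per-sample label container used throughout the package,
#' e.g. to feed externally defined (or simulated ground-truth) labels into
#' the classification, matching and characterization stages.
#'
#' @param sample_id character sample ids.
#' @param subtype subtype label per sample (`NA` for unlabelled).
#' @param core logical per sample; defaults to `!is.na(subtype)`.
#' @return A `subtype_assignment` data.frame.
#' @export
subtype_assignment <- function(sample_id, subtype,
                               core = !is.na(subtype)) {
  stopifnot(length(sample_id) == length(subtype),
            length(core) == length(subtype))
  out <- data.frame(sample_id = as.character(sample_id),
                    subtype = factor(subtype), core = as.logical(core),
                    stringsAsFactors = FALSE)
  if (any(out$core & is.na(out$subtype)))
    stop("every core sample needs a subtype label")
  attr(out, "sizes") <- table(out$subtype)
  class(out) <- c("subtype_assignment", "data.frame")
  out
}

#' Read / write a subtype assignment as TSV
#'
#' Columns `sample_id`, `subtype` (`NA` for non-core), `core` (0/1).
#'
#' @param assignment a `subtype_assignment`.
#' @param path file path.
#' @return `write_assignment_tsv` invisibly returns `path`;
#'   `read_assignment_tsv` returns a `subtype_assignment`.
#' @export
write_assignment_tsv <- function(assignment, path) {
  df <- data.frame(sample_id = assignment$sample_id,
                   subtype = as.character(assignment$subtype),
                   core = as.integer(assignment$core))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_assignment_tsv
#' @export
read_assignment_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  out <- data.frame(sample_id = df$sample_id,
                    subtype = factor(df$subtype),
                    core = df$core == 1, stringsAsFactors = FALSE)
  attr(out, "sizes") <- table(out$subtype)
  class(out) <- c("subtype_assignment", "data.frame")
  out
}
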