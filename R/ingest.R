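#' Collapse probesets to genes by maximal variance
#'
#' For every gene the probeset with the highest sample variance is kept as
#' its representative row. Ties break to the lexicographically smallest
#' probeset id, so the result is deterministic.
#'
#' @param probe_matrix numeric matrix, probesets in rows (rownames =
#'   probeset ids), samples in columns.
#' @param map probeset-to-gene map: a data.frame with columns
#'   `probeset_id`, `gene_id` (many probesets to one gene), or a named
#'   character vector `probeset -> gene`.
#' @param dataset optional per-sample dataset labels passed through to the
#'   result.
#' @return An [expr_collection] with one row per gene, in order of first
#'   appearance of each gene among the input rows.
#' @export
collapse_probesets <- function(probe_matrix, map, dataset = NULL) {
  if (is.data.frame(map)) {
    stopifnot(all(c("probeset_id", "gene_id") %in% names(map)))
    map <- stats::setNames(as.character(map$gene_id),
                           as.character(map$probeset_id))
  }
  probes <- rownames(probe_matrix)
  if (is.null(probes)) stop("probe_matrix needs probeset rownames")
  missing_p <- setdiff(probes, names(map))
  if (length(missing_p))
    stop("unmapped probesets: ", paste(missing_p, collapse = ", "))
  gene_of <- map[probes]
  v <- apply(probe_matrix, 1, stats::var)
  # order candidates so the first row per gene is the winner:
  # variance decreasing, then probeset id increasing for ties
  ord <- order(gene_of, -v, probes, method = "radix")
  winners <- ord[!duplicated(gene_of[ord])]
  # restore order of first appearance of each gene in the input
  first_seen <- match(unique(gene_of), gene_of)
  winners <- winners[match(gene_of[first_seen], gene_of[winners])]
  out <- probe_matrix[winners, , drop = FALSE]
  rownames(out) <- unname(gene_of[winners])
  expr_collection(out, dataset = dataset, allow_missing = TRUE)
}

#' Non-specific variance filtering
#'
#' Keeps the `n_keep` genes with the largest interquartile range (IQR) of
#' expression across all samples, preserving the input gene order among the
#' kept genes. Genes with any missing value are dropped before scoring
#' (downstream clustering requires complete rows). Ties at the cutoff break
#' to the lexicographically smallest gene id.
#'
#' @param coll an [expr_collection].
#' @param n_keep number of genes to retain (`0 < n_keep <=` gene count after
#'   the missing-value drop).
#' @return The filtered [expr_collection].
#' @export
nonspecific_filter <- function(coll, n_keep) {
  stopifnot(inherits(coll, "expr_collection"))
  if (n_keep <= 0) stop("n_keep must be positive")
  v <- coll$values
  complete <- rowSums(!is.finite(v)) == 0
  if (!all(complete)) {
    message(sum(!complete), " gene(s) with missing values dropped")
    v <- v[complete, , drop = FALSE]
  }
  if (n_keep > nrow(v)) stop("n_keep exceeds number of (complete) genes")
  score <- apply(v, 1, stats::IQR)
  ord <- order(-score, rownames(v), method = "radix")
  keep <- sort(ord[seq_len(n_keep)])   # preserve input order among the kept
  expr_collection(v[keep, , drop = FALSE], dataset = coll$dataset)
}

#' Pool datasets into one collection on the common gene set
#'
#' Intersects gene ids across datasets, concatenates samples, records the
#' dataset label, and median-centres every gene within each dataset (the
#' minimal harmonization for pooling cohorts measured on different
#' platforms).
#'
#' @param datasets a list of [expr_collection]s (each usually a single
#'   cohort) or a single collection.
#' @param names optional dataset names; defaults to list names or `D1..Dk`.
#' @return A pooled, per-dataset median-centred [expr_collection].
#' @export
assemble_collection <- function(datasets, names = NULL) {
  if (inherits(datasets, "expr_collection")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1,
            all(vapply(datasets, inherits, TRUE, "expr_collection")))
  if (is.null(names)) {
    names <- base::names(datasets)
    if (is.null(names)) names <- sprintf("D%d", seq_along(datasets))
  }
  common <- Reduce(intersect, lapply(datasets, function(d) rownames(d$values)))
  if (length(common) == 0) stop("empty gene intersection across datasets")
  mats <- lapply(datasets, function(d) d$values[common, , drop = FALSE])
  all_ids <- unlist(lapply(mats, colnames))
  if (anyDuplicated(all_ids))
    for (i in seq_along(mats))
      colnames(mats[[i]]) <- paste(names[i], colnames(mats[[i]]), sep = ".")
  values <- do.call(cbind, mats)
  dataset <- rep(names, vapply(mats, ncol, 0L))
  median_center_by_dataset(
    expr_collection(values, dataset, allow_missing = TRUE))
}
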