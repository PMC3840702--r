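#' Pearson correlation distance
#'
#' `1 - r` between two expression profiles; 0 for identical direction, 2 for
#' perfect anti-correlation.
#'
#' @param x,y numeric vectors of equal length (>= 3), non-constant.
#' @return The distance `1 - cor(x, y)` in `[0, 2]`.
#' @export
correlation_distance <- function(x, y) {
  if (length(x) != length(y)) stop("vectors must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant vector")
  1 - stats::cor(x, y)
}

# Full correlation-distance matrix over the rows of m.
cor_dist_matrix <- function(m) {
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("correlation undefined for constant gene(s): ",
         paste(utils::head(rownames(m)[sds == 0], 5), collapse = ", "))
  1 - stats::cor(t(m))
}

#' Complete-linkage clustering of genes on correlation distance
#'
#' @param coll an [expr_collection] with complete (finite) rows.
#' @return An [stats::hclust] tree over genes.
#' @export
cluster_genes <- function(coll) {
  stopifnot(inherits(coll, "expr_collection"))
  if (nrow(coll$values) < 2) stop("need at least 2 genes")
  d <- stats::as.dist(cor_dist_matrix(coll$values))
  stats::hclust(d, method = "complete")
}

#' Dynamic-hybrid tree cut into gene modules
#'
#' Two-stage cut in the spirit of the dynamic hybrid method: (1) the
#' dendrogram is cut at `cut_height`; branches of at least `min_module_size`
#' genes become module seeds, all other genes start unassigned; (2) if
#' expression data are supplied, each unassigned gene is attached to the
#' module whose median profile it correlates with best, provided that
#' correlation reaches `assign_corr` — otherwise it stays unassigned.
#' Modules are labelled `M1, M2, ...` by decreasing size.
#'
#' @param tree an [stats::hclust] tree from [cluster_genes()].
#' @param min_module_size smallest allowed module (>= 2).
#' @param cut_height static cut height on the correlation-distance
#'   dendrogram (default 0.7, i.e. complete-linkage correlation >= 0.3
#'   within a branch).
#' @param coll optional [expr_collection] enabling the hybrid assignment
#'   stage.
#' @param assign_corr minimum correlation with a module median for stage-2
#'   assignment.
#' @return A `gene_module_set`: list with `modules` (named list module id ->
#'   gene ids), `unassigned` (gene ids), `robust` (logical per module, `NA`
#'   until screened) and `discarded` (named character of reasons).
#' @export
dynamic_cut <- function(tree, min_module_size = 5, cut_height = 0.7,
                        coll = NULL, assign_corr = 0.3) {
  stopifnot(inherits(tree, "hclust"))
  if (min_module_size < 2) stop("min_module_size must be >= 2")
  cl <- stats::cutree(tree, h = cut_height)
  sizes <- table(cl)
  seed_ids <- names(sizes)[sizes >= min_module_size]
  modules <- lapply(seed_ids, function(i) names(cl)[cl == i])
  unassigned <- names(cl)[!cl %in% as.integer(seed_ids)]

  if (!is.null(coll) && length(modules) && length(unassigned)) {
    meds <- vapply(modules,
                   function(g) apply(coll$values[g, , drop = FALSE], 2,
                                     stats::median),
                   numeric(ncol(coll$values)))
    keep_un <- logical(length(unassigned))
    for (i in seq_along(unassigned)) {
      g <- coll$values[unassigned[i], ]
      if (stats::sd(g) == 0) { keep_un[i] <- TRUE; next }
      r <- suppressWarnings(stats::cor(g, meds))
      r[is.na(r)] <- 0
      if (max(r) >= assign_corr) {
        j <- which.max(r)
        modules[[j]] <- c(modules[[j]], unassigned[i])
      } else keep_un[i] <- TRUE
    }
    unassigned <- unassigned[keep_un]
  }

  ord <- order(-vapply(modules, length, 0L))
  modules <- modules[ord]
  names(modules) <- sprintf("M%d", seq_along(modules))
  new_gene_module_set(modules, unassigned)
}

#' Construct a gene module set
#'
#' Wraps an externally defined (or simulated ground-truth) gene-to-module
#' assignment in the container used by the meta-gene and classification
#' stages. Modules must be disjoint.
#'
#' @param modules named list: module id -> character vector of gene ids.
#' @param unassigned gene ids not in any module.
#' @return A `gene_module_set`.
#' @export
gene_module_set <- function(modules, unassigned = character(0)) {
  stopifnot(is.list(modules))
  if (is.null(names(modules)) || any(!nzchar(names(modules))))
    stop("modules must be named")
  genes <- unlist(modules, use.names = FALSE)
  if (anyDuplicated(genes)) stop("modules must be disjoint")
  new_gene_module_set(modules, unassigned)
}

new_gene_module_set <- function(modules, unassigned,
                                robust = rep(NA, length(modules)),
                                discarded = character(0)) {
  names(robust) <- names(modules)
  structure(list(modules = modules, unassigned = unassigned,
                 robust = robust, discarded = discarded),
            class = "gene_module_set")
}

#' @export
print.gene_module_set <- function(x, ...) {
  cat(sprintf("gene_module_set: %d modules (%d genes), %d unassigned\n",
              length(x$modules), length(unlist(x$modules)),
              length(x$unassigned)))
  if (length(x$discarded))
    cat(sprintf("  discarded: %d (%s)\n", length(x$discarded),
                paste(unique(x$discarded), collapse = ", ")))
  invisible(x)
}

#' Discover gene modules in one call
#'
#' Convenience wrapper: [cluster_genes()] then [dynamic_cut()] with the
#' hybrid assignment stage enabled.
#'
#' @inheritParams dynamic_cut
#' @param coll an [expr_collection].
#' @return A `gene_module_set`.
#' @export
discover_modules <- function(coll, min_module_size = 5, cut_height = 0.7,
                             assign_corr = 0.3) {
  dynamic_cut(cluster_genes(coll), min_module_size = min_module_size,
              cut_height = cut_height, coll = coll,
              assign_corr = assign_corr)
}

#' Screen modules for cross-dataset robustness
#'
#' A module is robust when its mean within-module pairwise Pearson
#' correlation reaches `r_min` in every dataset of the collection.
#' Non-robust modules and modules overlapping the exclusion list (e.g.
#' gender-related genes) are marked discarded with a reason. Correlations
#' involving a gene that is constant within a dataset count as 0.
#'
#' @param modules a `gene_module_set`.
#' @param coll the [expr_collection] the modules were discovered in.
#' @param r_min robustness threshold on the per-dataset mean pairwise
#'   correlation (default 0.5).
#' @param exclude_genes genes whose presence discards a module
#'   (reason `"excluded-genes"`).
#' @return The `gene_module_set` with `robust` flags and `discarded`
#'   reasons (`"non-robust"` or `"excluded-genes"`) filled in.
#' @export
module_robustness <- function(modules, coll, r_min = 0.5,
                              exclude_genes = character(0)) {
  stopifnot(inherits(modules, "gene_module_set"),
            inherits(coll, "expr_collection"))
  unknown <- setdiff(unlist(modules$modules), rownames(coll$values))
  if (length(unknown))
    stop("module references unknown gene: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  ds <- levels(coll$dataset)
  if (length(ds) < 2)
    warning("robustness screen needs >= 2 datasets; all modules pass")

  robust <- stats::setNames(rep(TRUE, length(modules$modules)),
                            names(modules$modules))
  discarded <- character(0)
  for (m in names(modules$modules)) {
    g <- modules$modules[[m]]
    if (length(intersect(g, exclude_genes))) {
      robust[m] <- FALSE
      discarded[m] <- "excluded-genes"
      next
    }
    if (length(ds) < 2) next
    for (d in ds) {
      sub <- coll$values[g, coll$dataset == d, drop = FALSE]
      r <- suppressWarnings(stats::cor(t(sub)))
      r[is.na(r)] <- 0          # constant gene within the dataset
      mean_r <- mean(r[upper.tri(r)])
      if (is.na(mean_r) || mean_r < r_min) {
        robust[m] <- FALSE
        discarded[m] <- "non-robust"
        break
      }
    }
  }
  new_gene_module_set(modules$modules, modules$unassigned, robust, discarded)
}

#' Keep only robust modules
#'
#' @param modules a screened `gene_module_set`.
#' @return A `gene_module_set` containing only modules whose robustness flag
#'   is `TRUE` (or `NA`, if the screen was not run).
#' @export
robust_modules <- function(modules) {
  keep <- is.na(modules$robust) | modules$robust
  new_gene_module_set(modules$modules[keep], modules$unassigned,
                      modules$robust[keep], modules$discarded)
}

#' Read / write a gene-module assignment as TSV
#'
#' Two columns `gene_id`, `module_id`; unassigned genes carry `NA`.
#'
#' @param modules a `gene_module_set`.
#' @param path file path.
#' @return `write_modules_tsv` invisibly returns `path`;
#'   `read_modules_tsv` returns a `gene_module_set`.
#' @export
write_modules_tsv <- function(modules, path) {
  df <- data.frame(
    gene_id = c(unlist(modules$modules), modules$unassigned),
    module_id = c(rep(names(modules$modules),
                      lengths(modules$modules)),
                  rep(NA_character_, length(modules$unassigned))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_modules_tsv
#' @export
read_modules_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  assigned <- df[!is.na(df$module_id), ]
  new_gene_module_set(split(assigned$gene_id, assigned$module_id),
                      df$gene_id[is.na(df$module_id)])
}
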