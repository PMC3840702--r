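#' Fit the module-based subtyping model to an expression collection
#'
#' Runs the full unsupervised subtyping workflow on a pooled multi-dataset
#' collection: per-dataset median centring; optional non-specific filtering;
#' gene-module discovery (complete linkage on correlation distance +
#' dynamic-hybrid cut); cross-dataset robustness screening; meta-gene
#' computation (module medians, row median-centred); meta-gene clustering;
#' consensus-distance clustering of samples with dendrogram pruning into
#' core-sample subtypes; and training of the LDA subtype classifier on core
#' samples.
#'
#' @param coll an [expr_collection] (multi-dataset labels respected).
#' @param k intended number of subtypes (base-clustering `k` inside the
#'   consensus loop), default 5.
#' @param n_keep optional non-specific filter size (genes kept by IQR);
#'   `NULL` keeps all genes.
#' @param min_module_size smallest gene module (default 5).
#' @param cut_height dendrogram cut height for module discovery.
#' @param r_min per-dataset robustness threshold on mean within-module
#'   correlation.
#' @param exclude_genes genes whose modules are discarded (e.g.
#'   gender-related).
#' @param n_resamples,subsample_frac consensus-clustering resampling
#'   parameters (defaults 500 and 0.8).
#' @param prune_height consensus-dendrogram pruning height (default 0.2;
#'   see [define_subtypes()]).
#' @param min_subtype_size smallest admissible subtype; default
#'   `max(10, 3%)` of samples.
#' @param ridge LDA covariance ridge coefficient.
#' @param seed integer seed for the consensus resampling.
#' @return A `module_subtypes` object: list with `coll` (centred,
#'   filtered), `tree`, `modules`, `metagenes`, `metagene_clusters`,
#'   `consensus`, `assignment`, `lda` and `call`.
#' @seealso [predict.module_subtypes()], [match_subtypes()],
#'   [minimal_gene_sets()]
#' @export
module_subtypes <- function(coll, k = 5, n_keep = NULL,
                            min_module_size = 5, cut_height = 0.7,
                            r_min = 0.5, exclude_genes = character(0),
                            n_resamples = 500, subsample_frac = 0.8,
                            prune_height = 0.2, min_subtype_size = NULL,
                            ridge = 1e-6, seed = 1) {
  stopifnot(inherits(coll, "expr_collection"))
  cl <- match.call()
  coll <- median_center_by_dataset(coll)
  if (!is.null(n_keep)) coll <- nonspecific_filter(coll, n_keep)

  tree <- cluster_genes(coll)
  modules <- dynamic_cut(tree, min_module_size = min_module_size,
                         cut_height = cut_height, coll = coll)
  modules <- module_robustness(modules, coll, r_min = r_min,
                               exclude_genes = exclude_genes)
  mg <- compute_metagenes(coll, modules)
  mg_clusters <- cluster_metagenes(mg)
  cm <- consensus_matrix(mg, n_resamples = n_resamples,
                         subsample_frac = subsample_frac, k_base = k,
                         seed = seed)
  assignment <- define_subtypes(cm, prune_height = prune_height,
                                min_subtype_size = min_subtype_size)
  lda <- if (nlevels(assignment$subtype) >= 2)
    lda_train(mg, assignment, ridge = ridge) else NULL

  structure(list(coll = coll, tree = tree, modules = modules,
                 metagenes = mg, metagene_clusters = mg_clusters,
                 consensus = cm, assignment = assignment, lda = lda,
                 call = cl),
            class = "module_subtypes")
}

#' @export
print.module_subtypes <- function(x, ...) {
  cat("module_subtypes fit\n")
  cat(sprintf("  %d genes x %d samples (%d datasets)\n",
              nrow(x$coll$values), ncol(x$coll$values),
              nlevels(x$coll$dataset)))
  nr <- sum(is.na(x$modules$robust) | x$modules$robust)
  cat(sprintf("  %d modules discovered, %d robust\n",
              length(x$modules$modules), nr))
  cat(sprintf("  %d subtypes on %d core samples (%.1f%%)\n",
              nlevels(x$assignment$subtype), sum(x$assignment$core),
              100 * mean(x$assignment$core)))
  invisible(x)
}

#' @export
summary.module_subtypes <- function(object, ...) {
  sizes <- attr(object$assignment, "sizes")
  mods <- robust_modules(object$modules)$modules
  out <- list(n_genes = nrow(object$coll$values),
              n_samples = ncol(object$coll$values),
              n_datasets = nlevels(object$coll$dataset),
              n_modules = length(object$modules$modules),
              n_robust = length(mods),
              module_sizes = lengths(mods),
              discarded = object$modules$discarded,
              subtype_sizes = sizes,
              core_fraction = mean(object$assignment$core),
              metagene_clusters = table(object$metagene_clusters,
                                        useNA = "ifany"))
  class(out) <- "summary.module_subtypes"
  out
}

#' @export
print.summary.module_subtypes <- function(x, ...) {
  cat(sprintf("module_subtypes: %d genes, %d samples, %d datasets\n",
              x$n_genes, x$n_samples, x$n_datasets))
  cat(sprintf("modules: %d discovered, %d robust (sizes %d-%d)\n",
              x$n_modules, x$n_robust,
              min(x$module_sizes), max(x$module_sizes)))
  if (length(x$discarded)) {
    tab <- table(x$discarded)
    cat("discarded:", paste(sprintf("%s=%d", names(tab), tab),
                            collapse = ", "), "\n")
  }
  cat(sprintf("subtypes (%.1f%% core):\n", 100 * x$core_fraction))
  print(x$subtype_sizes)
  invisible(x)
}

#' Assign new samples to fitted subtypes
#'
#' Computes meta-genes for the new collection with the fitted modules
#' (after per-dataset median centring of the new data) and applies the
#' fitted LDA classifier.
#'
#' @param object a `module_subtypes` fit with a trained classifier.
#' @param newdata an [expr_collection]; genes must cover the fitted
#'   modules (a module member absent from `newdata` drops out of that
#'   module's median, with a warning).
#' @param ... ignored.
#' @return As [predict.subtype_lda()]: list with `class` and `posterior`.
#' @export
predict.module_subtypes <- function(object, newdata, ...) {
  stopifnot(inherits(newdata, "expr_collection"))
  if (is.null(object$lda)) stop("fit has no trained classifier")
  mods <- robust_modules(object$modules)$modules
  usable <- lapply(mods, intersect, rownames(newdata$values))
  if (any(lengths(usable) == 0))
    stop("module(s) with no genes in newdata: ",
         paste(names(usable)[lengths(usable) == 0], collapse = ", "))
  if (any(lengths(usable) < lengths(mods)))
    warning("some module genes are absent from newdata; medians use the rest")
  mg <- compute_metagenes(median_center_by_dataset(newdata),
                          usable[object$lda$metagenes])
  predict(object$lda, mg)
}

#' Heat-map style display of a subtyping fit
#'
#' Shows the meta-gene matrix with samples ordered by subtype (non-core
#' last) and meta-genes ordered by meta-gene cluster.
#'
#' @param x a `module_subtypes` fit.
#' @param ... passed to [graphics::image()].
#' @return Invisibly, `x`.
#' @export
plot.module_subtypes <- function(x, ...) {
  v <- x$metagenes$values
  sub <- x$assignment$subtype
  samp_ord <- order(addNA(sub), method = "radix")
  mg_ord <- order(addNA(x$metagene_clusters), method = "radix")
  v <- v[mg_ord, samp_ord, drop = FALSE]
  lim <- max(abs(v))
  image(x = seq_len(ncol(v)), y = seq_len(nrow(v)), z = t(v),
        zlim = c(-lim, lim),
        col = grDevices::hcl.colors(51, "Blue-Red 2"),
        xlab = "samples (by subtype)", ylab = "meta-genes (by cluster)",
        axes = FALSE, ...)
  axis(2, at = seq_len(nrow(v)), labels = rownames(v), las = 2,
       cex.axis = 0.6)
  bounds <- cumsum(table(addNA(sub)))
  abline(v = utils::head(bounds, -1) + 0.5, col = "white", lwd = 2)
  invisible(x)
}
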