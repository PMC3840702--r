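#' Minimal subtype gene signatures by multinomial elastic net
#'
#' Fits a multinomial elastic-net regression of core-sample subtype labels
#' on gene-level expression (per-gene standardized), chooses the penalty by
#' cross-validation, and reports the genes with nonzero coefficients per
#' subtype. Direction is assigned relative to the population: "up" when the
#' subtype mean of the gene exceeds the overall mean.
#'
#' @param coll an [expr_collection] (gene-level).
#' @param labels a `subtype_assignment`; core samples are used.
#' @param alpha elastic-net mixing parameter in (0, 1], default 0.5.
#' @param n_folds cross-validation folds (default 10), stratified by class.
#' @param lambda `"min"` (default) for the CV-minimizing penalty or `"1se"`.
#' @param seed integer seed for the fold assignment.
#' @return A `signature_set`: per subtype a list with `up_genes` and
#'   `down_genes`, plus `alpha` and the chosen `lambda`.
#' @export
minimal_gene_sets <- function(coll, labels, alpha = 0.5, n_folds = 10,
                              lambda = c("min", "1se"), seed = 1) {
  stopifnot(inherits(coll, "expr_collection"),
            inherits(labels, "subtype_assignment"))
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  lambda <- match.arg(lambda)
  lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  lab <- lab[labels$core & !is.na(lab)]
  common <- intersect(names(lab), colnames(coll$values))
  x <- t(coll$values[, common, drop = FALSE])
  y <- factor(lab[common])
  if (nlevels(y) < 2) stop("need at least 2 subtypes")

  fit <- with_seed(seed, {
    foldid <- make_stratified_folds(y, n_folds)
    for (attempt in 1:5) {
      ok <- all(vapply(seq_len(n_folds), function(f)
        nlevels(droplevels(y[foldid != f])) == nlevels(y), TRUE))
      if (ok) break
      warning("degenerate fold (class absent); refolding")
      foldid <- make_stratified_folds(y, n_folds)
      if (attempt == 5) stop("could not build non-degenerate folds")
    }
    glmnet::cv.glmnet(x, y, family = "multinomial", alpha = alpha,
                      foldid = foldid, standardize = TRUE,
                      type.measure = "deviance")
  })
  s <- if (lambda == "min") fit$lambda.min else fit$lambda.1se
  coefs <- glmnet::coef.glmnet(fit, s = s)
  pop_mean <- rowMeans(coll$values[, common, drop = FALSE])
  sets <- lapply(levels(y), function(k) {
    b <- as.matrix(coefs[[k]])[-1, 1]   # drop intercept
    genes <- names(b)[b != 0]
    cls_mean <- rowMeans(coll$values[genes, common[y == k], drop = FALSE])
    up <- genes[cls_mean - pop_mean[genes] > 0]
    list(up_genes = sort(up), down_genes = sort(setdiff(genes, up)))
  })
  names(sets) <- levels(y)
  structure(list(sets = sets, alpha = alpha, lambda = s,
                 lambda_rule = lambda),
            class = "signature_set")
}

make_stratified_folds <- function(y, n_folds) {
  foldid <- integer(length(y))
  for (k in levels(y)) {
    idx <- sample(which(y == k))
    foldid[idx] <- rep_len(sample(n_folds), length(idx))
  }
  foldid
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set (alpha=%.2f, lambda=%.4g [%s])\n",
              x$alpha, x$lambda, x$lambda_rule))
  for (k in names(x$sets))
    cat(sprintf("  %s: %d up, %d down\n", k,
                length(x$sets[[k]]$up_genes),
                length(x$sets[[k]]$down_genes)))
  invisible(x)
}

#' Write signatures as TSV (subtype, gene, direction)
#'
#' @param sig a `signature_set`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_signatures_tsv <- function(sig, path) {
  rows <- do.call(rbind, lapply(names(sig$sets), function(k) {
    s <- sig$sets[[k]]
    data.frame(subtype = k,
               gene = c(s$up_genes, s$down_genes),
               direction = rep(c("up", "down"),
                               c(length(s$up_genes),
                                 length(s$down_genes))))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
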