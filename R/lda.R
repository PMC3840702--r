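#' Train a multiclass linear discriminant on meta-genes
#'
#' Gaussian linear discriminant with class means, a pooled within-class
#' covariance and empirical priors, fitted on core samples only. The pooled
#' covariance is ridge-regularized as `Sigma + ridge * trace(Sigma)/p * I`,
#' which keeps the model well-posed when the number of meta-genes approaches
#' the class sizes; `ridge = 0` gives the plain LDA.
#'
#' @param mg a `metagene_matrix`.
#' @param labels a `subtype_assignment` (core samples are used), or a named
#'   factor of class labels (all used).
#' @param ridge ridge coefficient, default `1e-6`.
#' @return A `subtype_lda` model: class `means`, pooled `cov`, `priors`,
#'   `labels` (class names), `metagenes` (feature names).
#' @export
lda_train <- function(mg, labels, ridge = 1e-6) {
  stopifnot(inherits(mg, "metagene_matrix"))
  if (inherits(labels, "subtype_assignment")) {
    lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
    lab <- lab[labels$core]
  } else {
    lab <- stats::setNames(as.character(labels), names(labels))
  }
  lab <- lab[!is.na(lab)]
  common <- intersect(names(lab), colnames(mg$values))
  if (!length(common)) stop("no labelled samples found in meta-gene matrix")
  x <- t(mg$values[, common, drop = FALSE])
  y <- factor(lab[common])
  if (nlevels(y) < 2) stop("need at least 2 classes")
  cnt <- table(y)
  if (any(cnt < 3))
    stop("class with < 3 samples: ",
         paste(names(cnt)[cnt < 3], collapse = ", "))
  p <- ncol(x)
  means <- matrix(NA_real_, nlevels(y), p,
                  dimnames = list(levels(y), colnames(x)))
  for (k in levels(y))
    means[k, ] <- colMeans(x[y == k, , drop = FALSE])
  centered <- x - means[as.integer(y), , drop = FALSE]
  sigma <- crossprod(centered) / (nrow(x) - nlevels(y))
  if (ridge > 0)
    sigma <- sigma + diag(ridge * sum(diag(sigma)) / p, p)
  structure(list(means = means, cov = sigma,
                 priors = as.numeric(cnt) / length(y),
                 labels = levels(y), metagenes = rownames(mg$values)),
            class = "subtype_lda")
}

#' @export
print.subtype_lda <- function(x, ...) {
  cat(sprintf("subtype_lda: %d classes (%s), %d meta-genes\n",
              length(x$labels), paste(x$labels, collapse = ", "),
              length(x$metagenes)))
  invisible(x)
}

#' Predict subtypes with a trained discriminant
#'
#' @param object a `subtype_lda` model.
#' @param newdata a `metagene_matrix` whose rows include every meta-gene the
#'   model was trained on, or a meta-gene x sample matrix.
#' @param ... ignored.
#' @return A list with `class` (factor; ties break to the lexicographically
#'   smallest label) and `posterior` (sample x class matrix, rows sum to 1).
#' @export
predict.subtype_lda <- function(object, newdata, ...) {
  v <- if (inherits(newdata, "metagene_matrix")) newdata$values else newdata
  missing_mg <- setdiff(object$metagenes, rownames(v))
  if (length(missing_mg))
    stop("missing meta-gene row(s): ",
         paste(utils::head(missing_mg, 5), collapse = ", "))
  x <- t(v[object$metagenes, , drop = FALSE])
  ch <- chol(object$cov)
  # discriminant: x' S^-1 mu_k - mu_k' S^-1 mu_k / 2 + log pi_k
  minv_mu <- chol2inv(ch) %*% t(object$means)
  disc <- x %*% minv_mu -
    matrix(colSums(t(object$means) * minv_mu) / 2, nrow(x),
           length(object$labels), byrow = TRUE) +
    matrix(log(object$priors), nrow(x), length(object$labels), byrow = TRUE)
  colnames(disc) <- object$labels
  # stable softmax; which.max takes the first (= smallest label, as labels
  # are kept sorted) on exact ties
  ord <- order(object$labels)
  disc <- disc[, ord, drop = FALSE]
  post <- exp(disc - apply(disc, 1, max))
  post <- post / rowSums(post)
  cls <- factor(colnames(post)[apply(post, 1, which.max)],
                levels = colnames(post))
  names(cls) <- rownames(x)
  list(class = cls, posterior = post)
}
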