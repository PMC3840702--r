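#' Expression collection
#'
#' The universal input container: a gene-by-sample matrix of log2 expression
#' values plus a per-sample dataset (cohort/batch) label. Gene identifiers are
#' stable gene-level ids (Entrez-style); duplicates are not allowed.
#'
#' @param values numeric matrix, genes in rows (rownames = gene ids), samples
#'   in columns (colnames = sample ids).
#' @param dataset character or factor of length `ncol(values)` giving the
#'   dataset label of each sample. Defaults to a single dataset `"D1"`.
#' @param allow_missing logical; if `FALSE` (default) any non-finite value is
#'   an error. Missing values are tolerated only upstream of filtering.
#' @return An object of class `expr_collection`: a list with elements
#'   `values` (matrix) and `dataset` (factor).
#' @examples
#' m <- matrix(rnorm(20), 4, 5,
#'             dimnames = list(paste0("g", 1:4), paste0("s", 1:5)))
#' coll <- expr_collection(m)
#' coll
#' @export
expr_collection <- function(values, dataset = NULL, allow_missing = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have rownames (gene ids) and colnames (sample ids)")
  if (anyDuplicated(rownames(values)))
    stop("duplicate gene ids: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]),
               collapse = ", "))
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids")
  if (is.null(dataset)) dataset <- rep("D1", ncol(values))
  if (length(dataset) != ncol(values))
    stop("`dataset` must have one label per sample")
  dataset <- factor(as.character(dataset))
  if (anyNA(dataset)) stop("every sample needs a dataset label")
  if (!allow_missing && !all(is.finite(values)))
    stop("non-finite expression values (set allow_missing = TRUE upstream of filtering)")
  structure(list(values = values, dataset = dataset),
            class = "expr_collection")
}

#' @export
print.expr_collection <- function(x, ...) {
  cat(sprintf("expr_collection: %d genes x %d samples, %d dataset(s)\n",
              nrow(x$values), ncol(x$values), nlevels(x$dataset)))
  tab <- table(x$dataset)
  cat("  samples per dataset:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.expr_collection <- function(x) dim(x$values)

#' Subset an expression collection
#'
#' @param x an `expr_collection`.
#' @param i gene index (ids, positions or logical).
#' @param j sample index.
#' @param ... ignored.
#' @return An `expr_collection` restricted to the requested genes/samples.
#' @export
`[.expr_collection` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$values))
  if (missing(j)) j <- seq_len(ncol(x$values))
  expr_collection(x$values[i, j, drop = FALSE],
                  dataset = x$dataset[j], allow_missing = TRUE)
}

#' Median-centre each gene within each dataset
#'
#' Minimal cross-platform harmonization used before pooling cohorts: every
#' gene is centred to median zero separately in each dataset, so additive
#' per-dataset offsets cancel.
#'
#' @param coll an `expr_collection`.
#' @return The centred `expr_collection`.
#' @export
median_center_by_dataset <- function(coll) {
  stopifnot(inherits(coll, "expr_collection"))
  v <- coll$values
  for (d in levels(coll$dataset)) {
    idx <- coll$dataset == d
    med <- apply(v[, idx, drop = FALSE], 1, stats::median)
    v[, idx] <- v[, idx, drop = FALSE] - med
  }
  expr_collection(v, coll$dataset, allow_missing = TRUE)
}

#' Read / write an expression matrix as TSV
#'
#' The on-disk format is a plain TSV with the sample header in row 1 and gene
#' ids in column 1.
#'
#' @param path file path.
#' @param dataset per-sample dataset labels (recycled scalar allowed).
#' @return `read_expression_tsv` returns an `expr_collection`;
#'   `write_expression_tsv` invisibly returns `path`.
#' @export
read_expression_tsv <- function(path, dataset = NULL) {
  df <- utils::read.delim(path, header = TRUE, row.names = 1,
                          check.names = FALSE)
  m <- as.matrix(df)
  storage.mode(m) <- "double"
  if (!is.null(dataset) && length(dataset) == 1L)
    dataset <- rep(dataset, ncol(m))
  expr_collection(m, dataset = dataset, allow_missing = TRUE)
}

#' @rdname read_expression_tsv
#' @param coll an `expr_collection` to write.
#' @export
write_expression_tsv <- function(coll, path) {
  df <- data.frame(gene_id = rownames(coll$values), coll$values,
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a clinical table as TSV
#'
#' Plain TSV with a `sample_id` column, marker columns (0/1) and survival
#' endpoint columns `<endpoint>_time` / `<endpoint>_event`.
#'
#' @param clinical a clinical data.frame.
#' @param path file path.
#' @return `read_clinical_tsv` returns a data.frame;
#'   `write_clinical_tsv` invisibly returns `path`.
#' @export
read_clinical_tsv <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' @rdname read_clinical_tsv
#' @export
write_clinical_tsv <- function(clinical, path) {
  utils::write.table(clinical, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets in GMT format
#'
#' @param path a GMT file: one set per line, tab-separated
#'   (name, description, genes...).
#' @return A named list of character vectors of gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  sets <- lapply(strsplit(lines, "\t"), function(f) f[-(1:2)])
  names(sets) <- vapply(strsplit(lines, "\t"), `[`, "", 1L)
  sets
}
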