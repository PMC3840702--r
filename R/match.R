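#' Match validation clusters to discovery subtypes
#'
#' Combines two sources of evidence, as in cross-cohort subtype validation:
#' (a) Pearson correlations between one-versus-all moderated-t profiles of
#' every (validation cluster, discovery subtype) pair on the common gene
#' universe, and (b) cross-prediction: the discovery LDA applied to
#' validation meta-genes (computed with the discovery modules), summarized
#' as a majority vote per validation cluster. The final mapping is the
#' maximum-weight one-to-one assignment on the correlation matrix;
#' validation clusters whose best correlation is below `c_min` are flagged
#' `"novel"`, and assignments that contradict the majority vote are flagged
#' `"ambiguous"` rather than resolved.
#'
#' @param disc discovery results: a list (or [module_subtypes] fit) with
#'   `coll` ([expr_collection]), `assignment` (`subtype_assignment`),
#'   `modules` (`gene_module_set`) and `lda` (`subtype_lda`).
#' @param valid validation results: a list (or fit) with `coll` and
#'   `assignment` (its own clusters, any labels).
#' @param c_min minimum t-profile correlation for a cluster to be
#'   matchable (default 0.3).
#' @return A `subtype_match`: list with `mapping` (data.frame:
#'   `validation_cluster`, `discovery_subtype`, `correlation`, `votes`,
#'   `status` in matched/ambiguous/novel), `correlations` (validation x
#'   discovery matrix) and `votes` (confusion table of LDA predictions).
#' @export
match_subtypes <- function(disc, valid, c_min = 0.3) {
  common <- intersect(rownames(disc$coll$values),
                      rownames(valid$coll$values))
  if (length(common) < 50)
    stop("fewer than 50 common genes between collections")
  dc <- disc$coll[common, ]
  vc <- valid$coll[common, ]

  disc_sub <- levels(disc$assignment$subtype)
  valid_cl <- levels(valid$assignment$subtype)
  if (!length(disc_sub) || !length(valid_cl))
    stop("both collections must have at least one subtype")

  tprof_d <- vapply(disc_sub,
                    function(s) moderated_t_profile(dc, disc$assignment, s)$t,
                    numeric(length(common)))
  tprof_v <- vapply(valid_cl,
                    function(s) moderated_t_profile(vc, valid$assignment, s)$t,
                    numeric(length(common)))
  cors <- stats::cor(tprof_v, tprof_d)   # validation x discovery

  # LDA cross-prediction votes: validation meta-genes on discovery modules
  mods_d <- robust_modules(disc$modules)$modules
  usable <- lapply(mods_d, intersect, rownames(valid$coll$values))
  keep <- lengths(usable) > 0
  if (!all(keep))
    warning(sum(!keep), " discovery module(s) have no genes in validation")
  votes <- NULL
  if (!is.null(disc$lda) &&
      all(disc$lda$metagenes %in% names(usable)[keep])) {
    mg_v <- compute_metagenes(median_center_by_dataset(valid$coll),
                              usable[disc$lda$metagenes])
    pred <- predict(disc$lda, mg_v)$class
    lab_v <- stats::setNames(as.character(valid$assignment$subtype),
                             valid$assignment$sample_id)
    lab_v <- lab_v[valid$assignment$core]
    votes <- table(validation = factor(lab_v, levels = valid_cl),
                   predicted = pred[names(lab_v)])
  }

  # exact maximum-weight one-to-one assignment on the correlation matrix
  matchable <- valid_cl[apply(cors, 1, max) >= c_min]
  assign_to <- rep(NA_character_, length(valid_cl))
  names(assign_to) <- valid_cl
  if (length(matchable)) {
    sub_c <- cors[matchable, , drop = FALSE]
    nv <- nrow(sub_c); nd <- ncol(sub_c)
    best <- NULL; best_w <- -Inf
    perms <- all_permutations(max(nv, nd))
    for (p in perms) {
      # p maps positions of the larger side; take the injective restriction
      map <- if (nv <= nd) p[seq_len(nv)] else NULL
      if (nv <= nd) {
        w <- sum(sub_c[cbind(seq_len(nv), map)])
        if (w > best_w) { best_w <- w; best <- map }
      } else {
        rows <- p[seq_len(nd)]
        w <- sum(sub_c[cbind(rows, seq_len(nd))])
        if (w > best_w) {
          best_w <- w
          best <- rep(NA_integer_, nv); best[rows] <- seq_len(nd)
        }
      }
    }
    assign_to[matchable] <- ifelse(is.na(best), NA_character_,
                                   disc_sub[best])
  }

  majority <- rep(NA_character_, length(valid_cl))
  names(majority) <- valid_cl
  if (!is.null(votes) && nrow(votes))
    majority[rownames(votes)] <-
      colnames(votes)[apply(votes, 1, which.max)]

  status <- vapply(valid_cl, function(v) {
    if (max(cors[v, ]) < c_min) "novel"
    else if (is.na(assign_to[v])) "novel"
    else if (!is.na(majority[v]) && majority[v] != assign_to[v]) "ambiguous"
    else "matched"
  }, "")

  mapping <- data.frame(
    validation_cluster = valid_cl,
    discovery_subtype = assign_to,
    correlation = vapply(valid_cl, function(v)
      if (is.na(assign_to[v])) max(cors[v, ])
      else cors[v, assign_to[v]], 0),
    votes = majority,
    status = status,
    stringsAsFactors = FALSE)
  structure(list(mapping = mapping, correlations = cors, votes = votes),
            class = "subtype_match")
}

#' @export
print.subtype_match <- function(x, ...) {
  cat("subtype_match:\n")
  print(x$mapping, row.names = FALSE)
  invisible(x)
}

#' Write a subtype match report as TSV
#'
#' @param match a `subtype_match`.
#' @param path file path.
#' @return Invisibly, `path`.
#' @export
write_match_tsv <- function(match, path) {
  utils::write.table(match$mapping, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
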