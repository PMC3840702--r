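#' Prognostic value of meta-genes: IQR-standardized stratified Cox
#'
#' One Cox proportional-hazards model per meta-gene, with the meta-gene
#' divided by its interquartile range (so hazard ratios are per-IQR and
#' invariant to affine rescaling of the covariate), stratified by dataset,
#' Wald p-values, and BH adjustment across meta-genes. Meta-genes with zero
#' IQR are skipped with a flag.
#'
#' @param mg a `metagene_matrix`.
#' @param clinical a data.frame with `sample_id` and
#'   `<endpoint>_time` / `<endpoint>_event` columns (months, 0/1).
#' @param endpoint one of `"rfs"`, `"os"`, `"sar"`.
#' @param min_events minimum number of events required (default 10).
#' @return A data.frame: `metagene`, `hr` (per IQR), `lo`, `hi` (95% CI),
#'   `p` (Wald), `p_adj`, `n`, `events`, `skipped`.
#' @export
cox_metagene <- function(mg, clinical, endpoint = c("rfs", "os", "sar"),
                         min_events = 10) {
  stopifnot(inherits(mg, "metagene_matrix"))
  endpoint <- match.arg(endpoint)
  sv <- endpoint_surv(clinical, endpoint)
  common <- intersect(colnames(mg$values), sv$sample_id)
  sv <- sv[match(common, sv$sample_id), ]
  if (sum(sv$event, na.rm = TRUE) < min_events)
    stop("fewer than ", min_events, " events for endpoint ", endpoint)
  strat <- mg$dataset[match(common, colnames(mg$values))]
  out <- lapply(rownames(mg$values), function(m) {
    x <- mg$values[m, common]
    iqr <- stats::IQR(x)
    if (iqr == 0)
      return(data.frame(metagene = m, hr = NA_real_, lo = NA_real_,
                        hi = NA_real_, p = NA_real_, n = length(x),
                        events = sum(sv$event), skipped = TRUE))
    fit <- survival::coxph(
      survival::Surv(sv$time, sv$event) ~ I(x / iqr) + strata(strat))
    s <- summary(fit)
    data.frame(metagene = m, hr = s$conf.int[1, "exp(coef)"],
               lo = s$conf.int[1, "lower .95"],
               hi = s$conf.int[1, "upper .95"],
               p = s$coefficients[1, "Pr(>|z|)"],
               n = s$n, events = s$nevent, skipped = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res$p_adj <- bh_adjust(res$p)
  res
}

# Extract a (sample_id, time, event) frame for one endpoint; SAR rows exist
# only for relapsed samples.
endpoint_surv <- function(clinical, endpoint) {
  tcol <- paste0(endpoint, "_time")
  ecol <- paste0(endpoint, "_event")
  if (!all(c("sample_id", tcol, ecol) %in% names(clinical)))
    stop("clinical table lacks ", tcol, "/", ecol)
  out <- data.frame(sample_id = clinical$sample_id,
                    time = clinical[[tcol]], event = clinical[[ecol]],
                    stringsAsFactors = FALSE)
  out[!is.na(out$time) & !is.na(out$event), ]
}

#' Pairwise survival differences between subtypes
#'
#' Observations are truncated at `truncate_months` (later events count as
#' censored at the truncation time), all subtype pairs are compared with
#' the log-rank test, p-values are BH-adjusted, and Kaplan-Meier risk-table
#' counts are reported at the requested times.
#'
#' @param labels a `subtype_assignment`.
#' @param clinical clinical data.frame (see [cox_metagene]).
#' @param endpoint `"rfs"`, `"os"` or `"sar"`.
#' @param truncate_months truncation horizon, default 84 (7 years).
#' @param times risk-table time points (months).
#' @return A list with `pairwise` (data.frame: `group1`, `group2`,
#'   `chisq`, `p`, `p_adj`) and `risk_table` (subtype x time matrix of
#'   numbers at risk).
#' @export
subtype_survival <- function(labels, clinical,
                             endpoint = c("rfs", "os", "sar"),
                             truncate_months = 84,
                             times = seq(0, truncate_months, by = 12)) {
  stopifnot(inherits(labels, "subtype_assignment"))
  endpoint <- match.arg(endpoint)
  sv <- endpoint_surv(clinical, endpoint)
  lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  lab <- lab[labels$core & !is.na(lab)]
  sv <- sv[sv$sample_id %in% names(lab), ]
  sv$subtype <- lab[sv$sample_id]
  over <- sv$time > truncate_months
  sv$event[over] <- 0L
  sv$time[over] <- truncate_months

  subs <- sort(unique(sv$subtype))
  if (length(subs) < 2) stop("need >= 2 subtypes with endpoint data")
  pairs <- utils::combn(subs, 2)
  out <- apply(pairs, 2, function(pr) {
    d <- sv[sv$subtype %in% pr, ]
    if (sum(d$event) == 0 || length(unique(d$subtype)) < 2)
      return(data.frame(group1 = pr[1], group2 = pr[2],
                        chisq = NA_real_, p = NA_real_))
    sd <- survival::survdiff(survival::Surv(time, event) ~ subtype, data = d)
    data.frame(group1 = pr[1], group2 = pr[2], chisq = sd$chisq,
               p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE))
  })
  pw <- do.call(rbind, out)
  rownames(pw) <- NULL
  pw$p_adj <- bh_adjust(pw$p)

  fit <- survival::survfit(survival::Surv(time, event) ~ subtype, data = sv)
  sm <- summary(fit, times = times, extend = TRUE)
  risk <- matrix(sm$n.risk, nrow = length(subs), byrow = TRUE,
                 dimnames = list(subs, times))
  list(pairwise = pw, risk_table = risk)
}

#' Additive multivariate Cox model: subtype + markers + stage
#'
#' Fits, per endpoint, `Surv ~ subtype + covariates` on the samples with
#' complete covariate data. The reference subtype (default: the largest)
#' carries no row in the output. Non-convergence or separation is reported
#' per endpoint rather than raised.
#'
#' @param labels a `subtype_assignment`.
#' @param clinical clinical data.frame with marker/stage columns.
#' @param covariates columns of `clinical` to adjust for (factors/binary);
#'   default: whichever of `MSI`, `BRAFm`, `stage` are present.
#' @param reference reference subtype (default the largest).
#' @param endpoints endpoints to fit.
#' @return A data.frame: `endpoint`, `term`, `hr`, `lo`, `hi`, `p`,
#'   `converged`.
#' @export
multivariate_cox <- function(labels, clinical, covariates = NULL,
                             reference = NULL,
                             endpoints = c("rfs", "os", "sar")) {
  stopifnot(inherits(labels, "subtype_assignment"))
  if (is.null(covariates))
    covariates <- intersect(c("MSI", "BRAFm", "stage"), names(clinical))
  lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  lab <- lab[labels$core & !is.na(lab)]
  if (is.null(reference))
    reference <- names(which.max(table(lab)))
  out <- list()
  for (ep in endpoints) {
    sv <- endpoint_surv(clinical, ep)
    sv <- sv[sv$sample_id %in% names(lab), ]
    df <- data.frame(time = sv$time, event = sv$event,
                     subtype = stats::relevel(factor(lab[sv$sample_id]),
                                              ref = reference))
    for (cv in covariates)
      df[[cv]] <- clinical[[cv]][match(sv$sample_id, clinical$sample_id)]
    df <- df[stats::complete.cases(df), ]
    fml <- stats::as.formula(paste("survival::Surv(time, event) ~ subtype",
                                   if (length(covariates))
                                     paste("+", covariates,
                                           collapse = " ") else ""))
    fit <- tryCatch(survival::coxph(fml, data = df),
                    error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit)) {
      out[[length(out) + 1L]] <- data.frame(
        endpoint = ep, term = NA_character_, hr = NA_real_, lo = NA_real_,
        hi = NA_real_, p = NA_real_, converged = FALSE)
      next
    }
    s <- summary(fit)
    out[[length(out) + 1L]] <- data.frame(
      endpoint = ep, term = rownames(s$coefficients),
      hr = s$conf.int[, "exp(coef)"], lo = s$conf.int[, "lower .95"],
      hi = s$conf.int[, "upper .95"], p = s$coefficients[, "Pr(>|z|)"],
      converged = TRUE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
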