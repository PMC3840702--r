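#' One-versus-all moderated t profile
#'
#' Per-gene empirical-Bayes moderated t statistics comparing one subtype's
#' core samples with all other core samples. The gene-wise pooled variance
#' s2 (residual df `d = n1 + n2 - 2`) is shrunk towards a prior variance
#' `s0^2` with prior df `d0`:
#' `s_tilde^2 = (d0 * s0^2 + d * s2) / (d0 + d)`, and
#' `t_tilde = (m1 - m2) / (s_tilde * sqrt(1/n1 + 1/n2))`.
#' The hyperparameters `(d0, s0^2)` are estimated by moment matching of the
#' scaled-F model for the gene variances, via the mean and variance of
#' `log s2` (digamma/trigamma closed forms). `d0 = 0` recovers the ordinary
#' pooled t; `d0 = Inf` uses `s0^2` for every gene.
#'
#' @param coll an [expr_collection] (the filtered gene universe).
#' @param labels a `subtype_assignment`; only core samples enter.
#' @param subtype the subtype compared against the rest (>= 3 core samples).
#' @param d0,s02 optionally force the prior df and prior variance instead of
#'   estimating them.
#' @return A `moderated_t` list: `t` (named per gene), `t_ordinary`, `s2`,
#'   `df` (residual df), `d0`, `s02`, `zero_variance` (logical flag per
#'   gene; such genes get `t = 0`), and `p` (two-sided, on `d0 + df` df).
#' @export
moderated_t_profile <- function(coll, labels, subtype, d0 = NULL,
                                s02 = NULL) {
  stopifnot(inherits(coll, "expr_collection"),
            inherits(labels, "subtype_assignment"))
  lab <- stats::setNames(as.character(labels$subtype), labels$sample_id)
  lab <- lab[labels$core & !is.na(lab)]
  common <- intersect(names(lab), colnames(coll$values))
  lab <- lab[common]
  if (!subtype %in% lab) stop("unknown or empty subtype: ", subtype)
  g1 <- common[lab == subtype]
  g2 <- common[lab != subtype]
  if (length(g1) < 3) stop("subtype needs >= 3 core samples")
  if (!length(g2)) stop("complement is empty")
  moderated_t_two_group(coll$values[, g1, drop = FALSE],
                        coll$values[, g2, drop = FALSE],
                        d0 = d0, s02 = s02)
}

# Core two-group moderated-t computation on row-matched matrices.
moderated_t_two_group <- function(x1, x2, d0 = NULL, s02 = NULL) {
  n1 <- ncol(x1); n2 <- ncol(x2)
  d <- n1 + n2 - 2
  m1 <- rowMeans(x1); m2 <- rowMeans(x2)
  ss1 <- rowSums((x1 - m1)^2)
  ss2 <- rowSums((x2 - m2)^2)
  s2 <- (ss1 + ss2) / d
  zero_var <- s2 <= 0

  if (is.null(d0) || is.null(s02)) {
    est <- estimate_variance_prior(s2[!zero_var], d)
    if (is.null(d0)) d0 <- est$d0
    if (is.null(s02)) s02 <- est$s02
  }
  if (d0 < 0) stop("d0 must be >= 0")

  s2_tilde <- if (is.infinite(d0)) rep(s02, length(s2))
              else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(s2_tilde * (1 / n1 + 1 / n2))
  tt <- (m1 - m2) / se
  tt[zero_var & (d0 == 0 | s2_tilde <= 0)] <- 0
  tt[!is.finite(tt)] <- 0
  t_ord <- (m1 - m2) / sqrt(s2 * (1 / n1 + 1 / n2))
  t_ord[zero_var] <- 0
  df_total <- if (is.infinite(d0)) Inf else d0 + d
  p <- 2 * stats::pt(-abs(tt), df = df_total)
  structure(list(t = tt, t_ordinary = t_ord, s2 = s2, df = d,
                 d0 = d0, s02 = s02, zero_variance = zero_var, p = p,
                 n1 = n1, n2 = n2, diff = m1 - m2),
            class = "moderated_t")
}

#' Estimate the variance-prior hyperparameters (d0, s0^2)
#'
#' Moment matching for the scaled-F model of gene-wise sample variances:
#' with `z = log(s2)`, `Var(z) = trigamma(d/2) + trigamma(d0/2)` and
#' `E(z) = log(s0^2) + digamma(d/2) - digamma(d0/2) + log(d0/d)`. The prior
#' df solves the trigamma equation (Newton inversion); non-positive excess
#' variance of `z` gives `d0 = Inf`.
#'
#' @param s2 positive gene-wise variances.
#' @param df their common residual df.
#' @return List with `d0` and `s02`.
#' @export
estimate_variance_prior <- function(s2, df) {
  s2 <- s2[is.finite(s2) & s2 > 0]
  if (length(s2) < 2) return(list(d0 = Inf, s02 = mean(s2)))
  z <- log(s2)
  excess <- stats::var(z) - trigamma(df / 2)
  if (excess <= 0) {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(df / 2) + log(df / 2))
  } else {
    d0 <- 2 * trigamma_inverse(excess)
    s02 <- exp(mean(z) - digamma(df / 2) + digamma(d0 / 2) - log(d0 / df))
  }
  list(d0 = d0, s02 = s02)
}

# Invert the trigamma function by Newton iteration on 1/trigamma,
# which is nearly linear.
trigamma_inverse <- function(y) {
  if (y <= 0) return(Inf)
  if (y > 1e7) return(1 / sqrt(y))
  x <- 0.5 + 1 / y
  for (i in 1:50) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif) / x < 1e-10) break
  }
  x
}
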