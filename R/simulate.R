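#' Simulation configuration for synthetic expression collections
#'
#' Describes a multi-dataset expression collection with planted gene modules,
#' subtypes, batch effects, clinical markers and survival. Defaults encode a
#' down-scaled but realistically structured multi-cohort study: two cohorts of
#' 150 tumours, 600 genes of which 20 co-expression modules (5-30 genes,
#' within-module correlation 0.7) are planted, five subtypes that shift
#' distinct sparse sets of module latents, moderate cohort batch offsets, and
#' a fifth of samples that are ambiguous mixtures of two subtype centroids.
#'
#' Module structure follows a single-factor model: gene g in module m is
#' `mu_g + a * f_m + noise`, with the loading `a` chosen so the expected
#' pairwise within-module correlation equals `within_module_corr`.
#'
#' @param n_datasets number of cohorts (batches).
#' @param samples_per_dataset tumour samples per cohort.
#' @param n_genes total number of genes.
#' @param n_modules number of planted co-expression modules.
#' @param module_size_range integer `c(min, max)` module sizes.
#' @param n_subtypes number of planted subtypes.
#' @param within_module_corr target pairwise Pearson correlation of genes in
#'   the same module, in `[0, 1]`.
#' @param subtype_shift shift (log2 units, on the unit-variance module
#'   latent) applied to each subtype's affected modules, with random sign.
#' @param batch_sd standard deviation (log2) of additive per-dataset,
#'   per-gene offsets.
#' @param noise_sd standard deviation (log2) of i.i.d. gene-level noise.
#' @param noncore_fraction proportion of samples generated as 50/50 mixtures
#'   of two subtype centroids (ambiguous, flagged non-core in the truth).
#' @param marker_prevalence named numeric, baseline prevalence of each binary
#'   marker.
#' @param marker_or named list: for each marker, a named vector of odds
#'   ratios per subtype (omitted subtypes have OR 1). Must be finite and > 0.
#' @param survival_hr named vector of hazard ratios per subtype; the
#'   reference subtype must have HR 1.
#' @param censor_rate target proportion of censored relapse-free-survival
#'   observations, in `[0, 1)`.
#' @param seed integer seed fixing all randomness of the generator.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_datasets = 2,
                       samples_per_dataset = 150,
                       n_genes = 600,
                       n_modules = 20,
                       module_size_range = c(5, 30),
                       n_subtypes = 5,
                       within_module_corr = 0.7,
                       subtype_shift = 1.5,
                       batch_sd = 0.3,
                       noise_sd = 0.5,
                       noncore_fraction = 0.2,
                       marker_prevalence = c(MSI = 0.15, BRAFm = 0.10,
                                             KRASm = 0.40),
                       marker_or = list(MSI = c(S3 = 8), BRAFm = c(S3 = 6)),
                       survival_hr = c(S1 = 1, S2 = 0.8, S3 = 1.5, S4 = 2,
                                       S5 = 1.2),
                       censor_rate = 0.3,
                       seed = 1) {
  subs <- sprintf("S%d", seq_len(n_subtypes))
  # align the per-subtype tables with the requested number of subtypes:
  # entries for absent subtypes are dropped, absent hazard ratios default to 1
  marker_or <- lapply(marker_or, function(or) or[names(or) %in% subs])
  hr <- stats::setNames(rep(1, n_subtypes), subs)
  hr[intersect(names(survival_hr), subs)] <-
    survival_hr[intersect(names(survival_hr), subs)]
  survival_hr <- hr
  cfg <- list(n_datasets = n_datasets,
              samples_per_dataset = samples_per_dataset,
              n_genes = n_genes, n_modules = n_modules,
              module_size_range = module_size_range,
              n_subtypes = n_subtypes,
              within_module_corr = within_module_corr,
              subtype_shift = subtype_shift, batch_sd = batch_sd,
              noise_sd = noise_sd, noncore_fraction = noncore_fraction,
              marker_prevalence = marker_prevalence, marker_or = marker_or,
              survival_hr = survival_hr, censor_rate = censor_rate,
              seed = as.integer(seed))
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (n_modules * module_size_range[1] > n_genes)
      stop("infeasible sizes: module sizes exceed gene count")
    if (within_module_corr < 0 || within_module_corr > 1)
      stop("within_module_corr must be in [0, 1]")
    if (batch_sd < 0 || noise_sd < 0) stop("all sd must be >= 0")
    if (noncore_fraction < 0 || noncore_fraction >= 1)
      stop("noncore_fraction must be in [0, 1)")
    if (censor_rate < 0 || censor_rate >= 1)
      stop("censor_rate must be in [0, 1)")
    ors <- unlist(marker_or)
    if (length(ors) && (any(!is.finite(ors)) || any(ors <= 0)))
      stop("marker odds ratios must be finite and > 0")
    if (!any(survival_hr == 1))
      stop("the reference subtype must have hazard ratio 1")
  })
  invisible(cfg)
}

# Plant the module assignment and the per-subtype shift patterns.
# Patterns are rejection-sampled until pairwise correlations are <= 0.25:
# near-collinear patterns would not define distinct subtypes.
plant_structure <- function(cfg) {
  sizes <- sample(seq(cfg$module_size_range[1], cfg$module_size_range[2]),
                  cfg$n_modules, replace = TRUE)
  while (sum(sizes) > cfg$n_genes)
    sizes[which.max(sizes)] <- sizes[which.max(sizes)] - 1L
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_genes))
  mod_genes <- split(gene_ids[seq_len(sum(sizes))],
                     rep(seq_len(cfg$n_modules), sizes))
  names(mod_genes) <- sprintf("TM%02d", seq_len(cfg$n_modules))
  bg_genes <- setdiff(gene_ids, unlist(mod_genes))

  k <- cfg$n_subtypes
  shift <- matrix(0, 0, cfg$n_modules,
                  dimnames = list(NULL, names(mod_genes)))
  for (s in seq_len(k))
    shift <- rbind(shift, draw_shift_pattern(cfg, shift))
  rownames(shift) <- sprintf("S%d", seq_len(k))
  list(mod_genes = mod_genes, bg_genes = bg_genes, shift = shift)
}

# One subtype shift pattern, distinct (pairwise cor <= 0.25) from `existing`.
draw_shift_pattern <- function(cfg, existing) {
  n_affected <- min(max(3L, round(0.3 * cfg$n_modules)), cfg$n_modules)
  for (i in 1:1000) {
    row <- numeric(cfg$n_modules)
    mods <- sample(cfg$n_modules, n_affected)
    row[mods] <- sample(c(-1, 1), n_affected, TRUE) * cfg$subtype_shift
    if (!nrow(existing)) return(row)
    pc <- suppressWarnings(stats::cor(t(existing), row))
    pc[is.na(pc)] <- 0
    if (max(pc) <= 0.25) return(row)   # anti-correlated patterns are distinct
  }
  stop("could not draw a distinct subtype shift pattern")
}

# Factor loading giving expected within-module correlation rho when the
# latent has unit variance and gene noise has sd noise_sd.
factor_loading <- function(rho, noise_sd) {
  if (rho >= 1 || noise_sd == 0) return(1)
  noise_sd * sqrt(rho / (1 - rho))
}

#' Generate a synthetic multi-dataset expression collection
#'
#' Builds an [expr_collection] with planted co-expression modules (one latent
#' factor per module), subtype-specific shifts of a sparse set of module
#' latents, additive per-dataset batch offsets, ambiguous mixture samples,
#' binary markers and correlated survival endpoints — together with the full
#' ground truth needed to score recovery.
#'
#' @param config a [sim_config].
#' @return A `sim_collection` list: `expression` ([expr_collection]),
#'   `true_modules` (named list module -> gene ids), `true_subtypes`
#'   (named factor per sample), `true_core` (named logical per sample),
#'   `clinical` (data.frame of markers and survival), `shift_pattern`
#'   (subtype x module matrix of planted latent shifts), and `config`.
#' @export
generate_collection <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  with_seed(config$seed, generate_collection_impl(config))
}

generate_collection_impl <- function(cfg, structure = NULL) {
  n <- cfg$n_datasets * cfg$samples_per_dataset
  sample_ids <- sprintf("s%03d", seq_len(n))
  dataset <- rep(sprintf("D%d", seq_len(cfg$n_datasets)),
                 each = cfg$samples_per_dataset)

  if (is.null(structure)) structure <- plant_structure(cfg)
  mod_genes <- structure$mod_genes
  bg_genes <- structure$bg_genes
  shift <- structure$shift
  k <- nrow(shift)
  gene_ids <- sort(c(unlist(mod_genes, use.names = FALSE), bg_genes))
  cfg$n_genes <- length(gene_ids)

  # sample-level truth
  true_sub <- factor(sample(rownames(shift), n, replace = TRUE),
                     levels = rownames(shift))
  n_noncore <- round(cfg$noncore_fraction * n)
  noncore_idx <- if (n_noncore > 0) sample(n, n_noncore) else integer(0)
  true_core <- rep(TRUE, n)
  true_core[noncore_idx] <- FALSE

  # latent factor means per sample (mixtures for non-core samples)
  latent_mean <- shift[as.integer(true_sub), , drop = FALSE]
  for (i in noncore_idx) {
    other <- sample(setdiff(seq_len(k), as.integer(true_sub[i])), 1)
    latent_mean[i, ] <- 0.5 * (shift[as.integer(true_sub[i]), ] +
                                 shift[other, ])
  }
  f <- latent_mean + matrix(stats::rnorm(n * cfg$n_modules), n)

  # expression: factor model for module genes, iid background elsewhere
  a <- factor_loading(cfg$within_module_corr, cfg$noise_sd)
  total_sd <- sqrt(a^2 + cfg$noise_sd^2)
  mu <- stats::setNames(stats::rnorm(cfg$n_genes, 7, 1), gene_ids)
  x <- matrix(0, cfg$n_genes, n, dimnames = list(gene_ids, sample_ids))
  for (m in seq_along(mod_genes)) {
    g <- mod_genes[[m]]
    x[g, ] <- mu[g] +
      a * matrix(f[, m], length(g), n, byrow = TRUE) +
      cfg$noise_sd * matrix(stats::rnorm(length(g) * n), length(g))
  }
  if (length(bg_genes))
    x[bg_genes, ] <- mu[bg_genes] +
      total_sd * matrix(stats::rnorm(length(bg_genes) * n), length(bg_genes))

  # per-dataset, per-gene batch offsets
  if (cfg$batch_sd > 0)
    for (d in unique(dataset)) {
      off <- stats::rnorm(cfg$n_genes, 0, cfg$batch_sd)
      x[, dataset == d] <- x[, dataset == d] + off
    }

  names(true_core) <- sample_ids
  names(true_sub) <- sample_ids

  clinical <- generate_markers(true_sub, cfg$marker_or,
                               cfg$marker_prevalence,
                               seed = sample.int(2^31 - 1, 1))
  surv <- generate_survival(true_sub, cfg$survival_hr, cfg$censor_rate,
                            seed = sample.int(2^31 - 1, 1))
  clinical <- cbind(clinical, surv[, -1])
  clinical$dataset <- dataset

  structure(list(expression = expr_collection(x, dataset),
                 true_modules = mod_genes,
                 true_subtypes = true_sub,
                 true_core = true_core,
                 clinical = clinical,
                 shift_pattern = shift,
                 config = cfg),
            class = "sim_collection")
}

#' Generate an independent validation collection sharing the planted truth
#'
#' Draws a fresh collection (new samples, noise, batch offsets, clinical
#' data) from the same planted module assignment and subtype shift patterns
#' as an existing simulated collection — the discovery/validation pairing of
#' a multi-cohort study. Optionally appends extra subtypes with their own
#' distinct shift patterns, emulating a subtype present only in the
#' validation series.
#'
#' @param sim a `sim_collection` from [generate_collection()].
#' @param seed integer seed for the new draw.
#' @param extra_subtypes number of additional subtypes to plant (default 0).
#' @param config optional [sim_config] for the new draw (sample sizes,
#'   batch sd, ...); module/subtype structure fields are taken from the
#'   planted truth, and survival/marker tables must cover the extra
#'   subtypes when `extra_subtypes > 0`.
#' @return A `sim_collection`.
#' @export
generate_validation <- function(sim, seed, extra_subtypes = 0,
                                config = NULL) {
  stopifnot(inherits(sim, "sim_collection"))
  cfg <- if (is.null(config)) sim$config else config
  cfg$seed <- as.integer(seed)
  structure_ <- list(mod_genes = sim$true_modules,
                     bg_genes = setdiff(rownames(sim$expression$values),
                                        unlist(sim$true_modules)),
                     shift = sim$shift_pattern)
  with_seed(cfg$seed, {
    if (extra_subtypes > 0) {
      for (i in seq_len(extra_subtypes))
        structure_$shift <- rbind(structure_$shift,
                                  draw_shift_pattern(cfg, structure_$shift))
      k <- nrow(structure_$shift)
      rownames(structure_$shift) <- sprintf("S%d", seq_len(k))
      cfg$n_subtypes <- k
      hr <- cfg$survival_hr
      extra <- setdiff(rownames(structure_$shift), names(hr))
      cfg$survival_hr <- c(hr, stats::setNames(rep(1, length(extra)), extra))
    }
    generate_collection_impl(cfg, structure = structure_)
  })
}

#' @export
print.sim_collection <- function(x, ...) {
  cat(sprintf(paste0("sim_collection: %d genes x %d samples, %d modules, ",
                     "%d subtypes, %.0f%% non-core\n"),
              nrow(x$expression$values), ncol(x$expression$values),
              length(x$true_modules), nlevels(x$true_subtypes),
              100 * mean(!x$true_core)))
  invisible(x)
}

#' Generate correlated survival endpoints with subtype-proportional hazards
#'
#' Relapse-free survival (RFS) times are exponential with hazard proportional
#' to the subtype hazard ratio; censoring is independent uniform, calibrated
#' to the target censoring rate. Survival after relapse (SAR) is generated
#' for relapsed samples only, and overall survival (OS) is coupled as
#' `OS = RFS + SAR` for relapsed samples and `OS = RFS` otherwise, so
#' `RFS <= OS` holds for every sample. Times are in months; the baseline
#' median RFS is 60 months and median SAR 24 months.
#'
#' @param subtypes factor of subtype labels per sample.
#' @param hr named vector of hazard ratios, one per subtype level; the
#'   reference subtype must have HR 1.
#' @param censor_rate target censoring proportion in `[0, 1)`.
#' @param seed integer seed.
#' @return A data.frame with `sample_id`, `rfs_time`, `rfs_event`,
#'   `os_time`, `os_event`, `sar_time`, `sar_event` (`NA` unless relapsed).
#' @export
generate_survival <- function(subtypes, hr, censor_rate = 0.3, seed = 1) {
  subtypes <- as.factor(subtypes)
  if (!all(levels(subtypes) %in% names(hr)))
    stop("unknown subtype label: ",
         paste(setdiff(levels(subtypes), names(hr)), collapse = ", "))
  if (!any(hr[levels(subtypes)] == 1))
    stop("the reference subtype must have hazard ratio 1")
  if (censor_rate < 0 || censor_rate >= 1)
    stop("censor_rate must be in [0, 1)")
  n <- length(subtypes)
  ids <- names(subtypes)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  lam_rfs <- log(2) / 60 * hr[as.character(subtypes)]
  lam_sar <- log(2) / 24 * hr[as.character(subtypes)]
  with_seed(seed, {
    t_rfs <- stats::rexp(n, lam_rfs)
    c_rfs <- uniform_censor(lam_rfs, censor_rate, n)
    rfs_time <- pmin(t_rfs, c_rfs)
    rfs_event <- as.integer(t_rfs <= c_rfs)

    sar_time <- rep(NA_real_, n)
    sar_event <- rep(NA_integer_, n)
    rel <- rfs_event == 1
    if (any(rel)) {
      t_sar <- stats::rexp(sum(rel), lam_sar[rel])
      c_sar <- uniform_censor(lam_sar[rel], censor_rate, sum(rel))
      sar_time[rel] <- pmin(t_sar, c_sar)
      sar_event[rel] <- as.integer(t_sar <= c_sar)
    }
    os_time <- ifelse(rel, rfs_time + sar_time, rfs_time)
    os_event <- ifelse(rel, sar_event, 0L)
    data.frame(sample_id = ids, rfs_time = rfs_time, rfs_event = rfs_event,
               os_time = os_time, os_event = as.integer(os_event),
               sar_time = sar_time, sar_event = sar_event,
               stringsAsFactors = FALSE)
  })
}

# Uniform(0, u) censoring times with u chosen so the average censoring
# probability over the hazards `lam` is `rate`.
uniform_censor <- function(lam, rate, n) {
  if (rate == 0) return(rep(Inf, n))
  pcens <- function(u) mean((1 - exp(-lam * u)) / (lam * u)) - rate
  u <- stats::uniroot(pcens, lower = 1e-6, upper = 1e6)$root
  stats::runif(n, 0, u)
}

#' Generate binary markers with subtype-dependent log-odds
#'
#' Each marker is Bernoulli per sample with
#' `logit(p) = logit(prevalence) + log(OR_subtype)`.
#'
#' @param subtypes factor of subtype labels per sample.
#' @param marker_or named list: marker -> named vector of odds ratios per
#'   subtype (missing subtypes have OR 1). Must be finite and > 0.
#' @param prevalence named vector of baseline prevalences per marker.
#' @param seed integer seed.
#' @return A data.frame with `sample_id` and one 0/1 column per marker.
#' @export
generate_markers <- function(subtypes, marker_or, prevalence, seed = 1) {
  subtypes <- as.factor(subtypes)
  ors <- unlist(marker_or)
  if (length(ors) && (any(!is.finite(ors)) || any(ors <= 0)))
    stop("marker odds ratios must be finite and > 0")
  n <- length(subtypes)
  ids <- names(subtypes)
  if (is.null(ids)) ids <- sprintf("s%03d", seq_len(n))
  out <- data.frame(sample_id = ids, stringsAsFactors = FALSE)
  with_seed(seed, {
    for (mk in names(prevalence)) {
      or <- stats::setNames(rep(1, nlevels(subtypes)), levels(subtypes))
      if (mk %in% names(marker_or)) {
        given <- marker_or[[mk]]
        bad <- setdiff(names(given), levels(subtypes))
        if (length(bad))
          stop("unknown subtype in marker_or: ", paste(bad, collapse = ", "))
        or[names(given)] <- given
      }
      p <- stats::plogis(stats::qlogis(prevalence[[mk]]) +
                           log(or[as.character(subtypes)]))
      out[[mk]] <- stats::rbinom(n, 1, p)
    }
  })
  out
}
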