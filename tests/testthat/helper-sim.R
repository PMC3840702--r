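# Shared fixtures, all built in code.

# A small, fast collection with planted structure for unit tests.
quick_sim <- function(seed = 1, ...) {
  generate_collection(sim_config(
    n_datasets = 2, samples_per_dataset = 60, n_genes = 200, n_modules = 8,
    module_size_range = c(5, 12), n_subtypes = 3, seed = seed, ...))
}

# Named truth partition (gene -> module) of a sim_collection.
truth_partition <- function(sim) {
  stats::setNames(rep(names(sim$true_modules), lengths(sim$true_modules)),
                  unlist(sim$true_modules))
}

# Recovered partition (gene -> module) of a gene_module_set.
recovered_partition <- function(modules) {
  stats::setNames(rep(names(modules$modules), lengths(modules$modules)),
                  unlist(modules$modules))
}

# ARI between a fitted assignment and the planted subtype truth, scored on
# samples that are core in both.
core_recovery <- function(fit_assignment, sim) {
  tc <- sim$true_core[fit_assignment$sample_id]
  ts <- sim$true_subtypes[fit_assignment$sample_id]
  both <- fit_assignment$core & tc
  list(ari = adjusted_rand_index(as.character(fit_assignment$subtype[both]),
                                 as.character(ts[both])),
       noncore_recall = mean(!fit_assignment$core[!tc]))
}

# Wrap simulated truth labels as a subtype_assignment.
truth_assignment <- function(sim, core_only = FALSE) {
  core <- if (core_only) sim$true_core else rep(TRUE, length(sim$true_core))
  subtype_assignment(names(sim$true_subtypes),
                     as.character(sim$true_subtypes), core)
}

# Majority map from fitted subtype labels to planted subtype labels.
majority_map <- function(assignment, sim) {
  lab <- as.character(assignment$subtype[assignment$core])
  tru <- as.character(sim$true_subtypes[assignment$sample_id[assignment$core]])
  tapply(tru, lab, function(v) names(which.max(table(v))))
}

# A deterministic small expression matrix.
toy_matrix <- function(n_genes = 6, n_samples = 10, seed = 42) {
  withr::with_seed(seed, {
    m <- matrix(rnorm(n_genes * n_samples), n_genes, n_samples)
    dimnames(m) <- list(sprintf("g%02d", seq_len(n_genes)),
                        sprintf("s%02d", seq_len(n_samples)))
    m
  })
}
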