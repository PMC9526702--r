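# Small, fast simulation settings shared across test files. Unit tests run
# at reduced scale; the acceptance tests use the full default configuration.

small_config <- function(seed = 1L, ...) {
  args <- list(n_proteins = 600, n_patients = 8, duplicates_per_region = 2,
               n_signature_per_niche = 40, n_bulk = 60, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# fully observed toy matrix with deterministic values
toy_matrix <- function(values, scale_tag = "log2", group = NULL) {
  meta <- data.frame(sample_id = colnames(values), stringsAsFactors = FALSE)
  if (!is.null(group)) meta$group <- group
  protein_matrix(values, meta, scale_tag = scale_tag)
}

# preprocess a synthetic atlas + bulk pair up to z-scored matrices
prep_pair <- function(atlas, bulk, seed = 11L) {
  am <- filter_by_group_presence(atlas$matrix)
  am <- impute_downshifted_gaussian(am, imputation_params(seed = seed))
  bm <- impute_downshifted_gaussian(bulk$matrix, imputation_params(seed = seed + 1L))
  sh <- intersect_features(am, bm)
  list(atlas = zscore_within_sample(sh$a), bulk = zscore_within_sample(sh$b))
}

true_dominant <- function(bulk) {
  colnames(bulk$true_weights)[apply(bulk$true_weights, 1, which.max)]
}
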