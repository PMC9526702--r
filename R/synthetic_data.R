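#' Simulation configuration for synthetic atlases and bulk cohorts
#'
#' Defines the generative model used throughout the test suite: a reference
#' atlas of laser-capture-microdissected niche regions (LFQ-like scale,
#' patient random effects, technical duplicates, left-censored missingness)
#' and a bulk cohort of niche mixtures on a shifted TMT-like scale with
#' subtype-dependent Dirichlet weights.
#'
#' @param n_proteins number of proteins (default 4794, the atlas scale).
#' @param n_patients reference patients (default 20).
#' @param duplicates_per_region technical duplicates per microdissected
#'   region (default 2), giving 5 x n_patients x duplicates reference columns.
#' @param n_signature_per_niche niche-marker proteins per niche (default 100).
#' @param signature_effect log2-fold elevation of a marker in its own niche
#'   (default 2).
#' @param patient_sd between-patient SD of the random intercept, log2 units
#'   (default 0.5).
#' @param noise_sd residual SD, log2 units (default 0.5).
#' @param missing_censor_quantile fraction of low-intensity values censored
#'   (default 0.1); censoring is intensity-dependent (MNAR).
#' @param n_bulk bulk cohort size (default 110).
#' @param dirichlet_alpha base Dirichlet concentration per niche (default 1).
#' @param subtype_coupling named list mapping a subtype to
#'   `list(niche =, factor =)`; that niche's Dirichlet alpha is multiplied by
#'   `factor` for samples of that subtype. Default couples proneural to IT
#'   (factor 6). Use `list()` for no coupling.
#' @param subtype_prop named numeric of subtype frequencies over
#'   [SUBTYPE_LEVELS]; default 0.25/0.25/0.30/0.10/0.10.
#' @param platform_scale,platform_shift affine transform (`a*x + b`) applied
#'   to the bulk matrix so its scale differs from the reference scale
#'   (defaults 0.8 and 5), forcing the z-score harmonization step to matter.
#' @param baseline_mean,baseline_sd distribution of per-protein baseline
#'   log2 abundances (defaults 25 and 2, LFQ-like).
#' @param seed integer RNG seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 4794, n_patients = 20,
                       duplicates_per_region = 2,
                       n_signature_per_niche = 100, signature_effect = 2,
                       patient_sd = 0.5, noise_sd = 0.5,
                       missing_censor_quantile = 0.1,
                       n_bulk = 110, dirichlet_alpha = 1,
                       subtype_coupling = list(
                         proneural = list(niche = "IT", factor = 6)),
                       subtype_prop = c(proneural = 0.25, classical = 0.25,
                                        mesenchymal = 0.30, `IDH-mutant` = 0.10,
                                        normal = 0.10),
                       platform_scale = 0.8, platform_shift = 5,
                       baseline_mean = 25, baseline_sd = 2,
                       seed = 1L) {
  subtype_prop <- unlist(subtype_prop)   # tolerate list form (config files)
  dirichlet_alpha <- unlist(dirichlet_alpha)
  cfg <- as.list(environment())
  cfg$cfg <- NULL
  stopifnot(n_proteins > 0, n_patients > 0, duplicates_per_region > 0,
            n_signature_per_niche >= 0, n_bulk > 0,
            patient_sd >= 0, noise_sd >= 0,
            missing_censor_quantile >= 0, missing_censor_quantile < 1,
            all(dirichlet_alpha > 0))
  if (n_signature_per_niche * 5 > n_proteins)
    stop("n_signature_per_niche x 5 exceeds n_proteins")
  for (cp in subtype_coupling) {
    stopifnot(cp$niche %in% NICHE_LEVELS, cp$factor > 0)
  }
  stopifnot(all(names(subtype_prop) %in% SUBTYPE_LEVELS), all(subtype_prop >= 0))
  structure(cfg, class = "sim_config")
}

# niche mean log2 profiles and marker assignment, given baselines
make_truth <- function(config, baseline) {
  p <- config$n_proteins
  markers <- vector("list", 5)
  names(markers) <- NICHE_LEVELS
  niche_means <- matrix(rep(baseline, 5), nrow = p, ncol = 5,
                        dimnames = list(names(baseline), NICHE_LEVELS))
  k <- config$n_signature_per_niche
  for (i in seq_along(NICHE_LEVELS)) {
    idx <- seq.int((i - 1) * k + 1, length.out = k)
    markers[[i]] <- names(baseline)[idx]
    niche_means[idx, i] <- niche_means[idx, i] + config$signature_effect
  }
  list(niche_means = niche_means, markers = markers)
}

# MNAR censoring: drop x_ij when x_ij + eps falls below the matrix-wide
# quantile of the same noisy proxy; eps ~ N(0, 0.5)
censor_mnar <- function(vals, q) {
  if (q <= 0) return(vals)
  proxy <- vals + stats::rnorm(length(vals), 0, 0.5)
  vals[proxy < stats::quantile(proxy, q)] <- NA_real_
  vals
}

#' Generate a synthetic reference niche atlas
#'
#' Emulates a microdissected glioblastoma niche atlas: each column is one
#' technical duplicate of one niche region from one patient. Values are
#' log2-intensity-like: protein baseline + niche marker effect + patient
#' random intercept + residual noise, with intensity-dependent (MNAR)
#' left-censoring. Generative ground truth (niche mean profiles, marker
#' sets, patient effects) is stored in `$truth`.
#'
#' @param config a [sim_config()].
#' @return A list of class `reference_atlas` with elements `matrix`
#'   (a [protein_matrix()], scale_tag `"log2"`), `niche_of_sample` (named
#'   character) and `truth`.
#' @export
generate_reference_atlas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  p <- config$n_proteins
  prot <- sprintf("P%04d", seq_len(p))
  baseline <- stats::rnorm(p, config$baseline_mean, config$baseline_sd)
  names(baseline) <- prot
  truth <- make_truth(config, baseline)

  pats <- sprintf("pt%02d", seq_len(config$n_patients))
  pat_eff <- stats::rnorm(config$n_patients, 0, config$patient_sd)
  names(pat_eff) <- pats

  grid <- expand.grid(dup = seq_len(config$duplicates_per_region),
                      niche = NICHE_LEVELS, patient = pats,
                      stringsAsFactors = FALSE)
  n <- nrow(grid)
  sample_id <- sprintf("ref_%s_%s_d%d", grid$patient, grid$niche, grid$dup)
  vals <- truth$niche_means[, grid$niche, drop = FALSE] +
    rep(pat_eff[grid$patient], each = p) +
    stats::rnorm(p * n, 0, config$noise_sd)
  dimnames(vals) <- list(prot, sample_id)
  vals <- censor_mnar(vals, config$missing_censor_quantile)

  meta <- data.frame(sample_id = sample_id, patient = grid$patient,
                     group = grid$niche, platform = "LFQ",
                     stringsAsFactors = FALSE)
  niche_of_sample <- stats::setNames(grid$niche, sample_id)
  truth$patient_effects <- pat_eff
  truth$config <- config
  structure(list(matrix = protein_matrix(vals, meta, "log2"),
                 niche_of_sample = niche_of_sample,
                 truth = truth),
            class = "reference_atlas")
}

#' @export
print.reference_atlas <- function(x, ...) {
  cat(sprintf("reference_atlas: %d samples, niches %s\n",
              ncol(x$matrix$values),
              paste(table(factor(x$niche_of_sample, NICHE_LEVELS)), collapse = "/")))
  print(x$matrix)
  invisible(x)
}

# Dirichlet draw via gamma normalization
rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (all(g == 0)) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Generate a synthetic bulk cohort of niche mixtures
#'
#' Each bulk sample's expected log2 profile is the weighted arithmetic mean
#' of the five niche mean profiles (mixing on the log scale, matching what
#' the z-scored classifier consumes), with per-sample Dirichlet weights whose
#' concentration is tilted by the subtype-niche coupling in `config`.
#' Normal-control samples use weight 1 on LE. A global affine platform shift
#' is applied so the bulk scale differs from the reference scale, and the
#' same MNAR censoring as the atlas is used. True mixture weights are
#' recorded in `$true_weights`.
#'
#' @param atlas a synthetic [generate_reference_atlas()] output (must carry
#'   `$truth`).
#' @param config a [sim_config()]; `n_bulk`, `dirichlet_alpha`,
#'   `subtype_coupling`, `subtype_prop` and the platform transform are read
#'   from here.
#' @param seed optional seed overriding `config$seed` (so several cohorts
#'   can be drawn from one atlas).
#' @return A list of class `bulk_cohort` with elements `matrix`
#'   (a [protein_matrix()], scale_tag `"log2"`), `subtype_of_sample` (named
#'   character) and `true_weights` (n_bulk x 5 matrix, rows on the simplex).
#' @export
generate_bulk_cohort <- function(atlas, config, seed = NULL) {
  stopifnot(inherits(atlas, "reference_atlas"), inherits(config, "sim_config"))
  if (is.null(atlas$truth))
    stop("atlas carries no generative truth; bulk cohorts require a synthetic atlas")
  set.seed(if (is.null(seed)) config$seed + 1L else seed)
  nm <- atlas$truth$niche_means
  p <- nrow(nm)
  n <- config$n_bulk

  prop <- config$subtype_prop[SUBTYPE_LEVELS]
  prop[is.na(prop)] <- 0
  subtype <- sample(SUBTYPE_LEVELS, n, replace = TRUE, prob = prop)
  base_alpha <- rep(config$dirichlet_alpha, length.out = 5)
  names(base_alpha) <- NICHE_LEVELS

  W <- matrix(0, n, 5, dimnames = list(NULL, NICHE_LEVELS))
  for (j in seq_len(n)) {
    if (subtype[j] == "normal") {
      W[j, "LE"] <- 1
    } else {
      a <- base_alpha
      cp <- config$subtype_coupling[[subtype[j]]]
      if (!is.null(cp)) a[cp$niche] <- a[cp$niche] * cp$factor
      W[j, ] <- rdirichlet1(a)
    }
  }

  sample_id <- sprintf("bulk_%03d", seq_len(n))
  vals <- nm %*% t(W) + stats::rnorm(p * n, 0, config$noise_sd)
  vals <- config$platform_scale * vals + config$platform_shift
  dimnames(vals) <- list(rownames(nm), sample_id)
  vals <- censor_mnar(vals, config$missing_censor_quantile)
  rownames(W) <- sample_id

  meta <- data.frame(sample_id = sample_id, patient = sample_id,
                     group = subtype, platform = "TMT",
                     stringsAsFactors = FALSE)
  structure(list(matrix = protein_matrix(vals, meta, "log2"),
                 subtype_of_sample = stats::setNames(subtype, sample_id),
                 true_weights = W),
            class = "bulk_cohort")
}

#' @export
print.bulk_cohort <- function(x, ...) {
  cat(sprintf("bulk_cohort: %d samples (%s)\n", ncol(x$matrix$values),
              paste(names(table(x$subtype_of_sample)),
                    table(x$subtype_of_sample), sep = "=", collapse = ", ")))
  print(x$matrix)
  invisible(x)
}

#' Spike a differential signal into a matrix
#'
#' Adds `delta` (log2 units) to the named proteins in the samples of
#' `groupA` only, and records the spiked set in the `spiked` attribute for
#' later recovery scoring. A volcano analysis contrasting `groupA` against
#' the remaining samples should recover the spiked proteins.
#'
#' @param matrix a [protein_matrix()].
#' @param groupA character vector of sample ids receiving the shift.
#' @param proteins character vector of protein ids to shift.
#' @param delta log2 shift to add.
#' @return A copy of `matrix` with the shift applied and
#'   `attr(, "spiked")` set to `proteins`.
#' @export
spike_differential <- function(matrix, groupA, proteins, delta) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (!all(groupA %in% sample_ids(matrix)))
    stop("unknown sample ids in groupA")
  if (length(proteins) == 0) {
    warning("empty protein set; returning matrix unchanged")
    attr(matrix, "spiked") <- character()
    return(matrix)
  }
  if (!all(proteins %in% protein_ids(matrix)))
    stop("unknown protein ids")
  matrix$values[proteins, groupA] <- matrix$values[proteins, groupA] + delta
  attr(matrix, "spiked") <- proteins
  matrix
}

#' Write the generative ground truth of a synthetic object as JSON
#'
#' @param x a `reference_atlas` or `bulk_cohort`.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
write_truth_json <- function(x, path) {
  if (inherits(x, "reference_atlas")) {
    obj <- list(markers = x$truth$markers,
                patient_effects = as.list(x$truth$patient_effects))
  } else if (inherits(x, "bulk_cohort")) {
    obj <- list(true_weights = apply(x$true_weights, 1, as.list),
                subtype = as.list(x$subtype_of_sample))
  } else stop("no truth to write")
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
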