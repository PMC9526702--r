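#' Filter proteins by in-group presence
#'
#' Keeps a protein when there is at least one group in which it is observed
#' (non-missing) in at least `min_frac` of that group's samples. The
#' threshold is inclusive: 3 of 5 passes at `min_frac = 0.6`. Row order of
#' retained proteins is preserved, and the operation is idempotent.
#'
#' @param matrix a [protein_matrix()].
#' @param group_of_sample named character vector mapping every sample id to
#'   exactly one group; defaults to the `group` column of the sample
#'   metadata.
#' @param min_frac minimum presence fraction within a group, in (0, 1]
#'   (default 0.6).
#' @return The filtered [protein_matrix()].
#' @export
filter_by_group_presence <- function(matrix, group_of_sample = NULL,
                                     min_frac = 0.6) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (!(min_frac > 0 && min_frac <= 1)) stop("min_frac must be in (0, 1]")
  if (is.null(group_of_sample)) {
    if (!"group" %in% names(matrix$sample_meta))
      stop("no group_of_sample given and sample_meta has no 'group' column")
    group_of_sample <- stats::setNames(matrix$sample_meta$group,
                                       matrix$sample_meta$sample_id)
  }
  ids <- sample_ids(matrix)
  if (!all(ids %in% names(group_of_sample)))
    stop("every sample must be assigned to a group")
  grp <- group_of_sample[ids]
  if (anyNA(grp) || any(!nzchar(grp))) stop("a group with zero samples / missing assignment")
  present <- !is.na(matrix$values)
  keep <- rep(FALSE, nrow(present))
  for (g in unique(grp)) {
    cols <- grp == g
    keep <- keep | (rowMeans(present[, cols, drop = FALSE]) >= min_frac)
  }
  subset_proteins(matrix, which(keep))
}

#' Log2-transform a raw-scale matrix
#'
#' @param matrix a [protein_matrix()] with `scale_tag = "raw"`; all present
#'   values must be positive. Missing values stay missing.
#' @return The matrix on log2 scale (`scale_tag = "log2"`).
#' @export
log2_transform <- function(matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  matrix <- advance_scale(matrix, "raw", "log2")
  bad <- which(!is.na(matrix$values) & matrix$values <= 0, arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop(sprintf("nonpositive value at protein '%s', sample '%s'",
                 protein_ids(matrix)[bad[1, 1]], sample_ids(matrix)[bad[1, 2]]))
  matrix$values <- log2(matrix$values)
  matrix
}

#' Imputation parameters for left-censored missing values
#'
#' Downshifted-Gaussian imputation in the Perseus style: missing entries of
#' a sample are drawn from `Normal(m - downshift*s, (width*s)^2)` where `m`
#' and `s` are the sample's observed mean and SD. The shipped default is the
#' printed parameterization (downshift 0.3, width 1.8);
#' [imputation_params_perseus()] gives the conventional Perseus preset
#' (downshift 1.8, width 0.3). Neither is asserted as the "correct" reading
#' of the published pair; both satisfy the same moment contract.
#'
#' @param downshift downshift in SD multiples (>= 0).
#' @param width width in SD multiples (> 0).
#' @param scope `"per_sample"` (column-wise moments, the default) or
#'   `"global"` (matrix-wide moments).
#' @param seed integer RNG seed.
#' @return A list of class `imputation_params`.
#' @export
imputation_params <- function(downshift = 0.3, width = 1.8,
                              scope = c("per_sample", "global"), seed = 1L) {
  stopifnot(downshift >= 0, width > 0)
  scope <- match.arg(scope)
  structure(list(downshift = downshift, width = width, scope = scope,
                 seed = as.integer(seed)), class = "imputation_params")
}

#' @rdname imputation_params
#' @export
imputation_params_perseus <- function(scope = c("per_sample", "global"), seed = 1L)
  imputation_params(downshift = 1.8, width = 0.3, scope = scope, seed = seed)

#' Impute missing values from a downshifted Gaussian
#'
#' Replaces each missing entry by a draw from a normal distribution shifted
#' below the observed values, emulating left-censored (MNAR) missingness.
#' Observed entries are never altered; the set of imputed cells equals the
#' set of missing cells; draws are seeded and reproducible.
#'
#' @param matrix a [protein_matrix()] with `scale_tag = "log2"`.
#' @param params an [imputation_params()].
#' @return The matrix with `scale_tag = "log2-imputed"`.
#' @export
impute_downshifted_gaussian <- function(matrix, params = imputation_params()) {
  stopifnot(inherits(matrix, "protein_matrix"), inherits(params, "imputation_params"))
  matrix <- advance_scale(matrix, "log2", "log2-imputed")
  miss <- is.na(matrix$values)
  if (!any(miss)) return(matrix)
  set.seed(params$seed)
  gm <- mean(matrix$values[!miss])
  gs <- stats::sd(matrix$values[!miss])
  for (j in seq_len(ncol(matrix$values))) {
    mj <- miss[, j]
    if (!any(mj)) next
    obs <- matrix$values[!mj, j]
    if (params$scope == "per_sample" && length(obs) >= 2) {
      m <- mean(obs); s <- stats::sd(obs)
    } else {
      if (params$scope == "per_sample")
        warning(sprintf("sample '%s' has < 2 observed values; using global moments",
                        sample_ids(matrix)[j]))
      m <- gm; s <- gs
    }
    matrix$values[mj, j] <- stats::rnorm(sum(mj), m - params$downshift * s,
                                         params$width * s)
  }
  matrix
}

#' Z-score each sample column
#'
#' Transforms every sample to `(x - mean)/sd` over its own values (sample SD,
#' denominator n-1). This is the harmonization step that puts reference
#' (LFQ-like) and bulk (TMT-like) matrices on a common scale before
#' classification; it is invariant to any prior per-column affine transform
#' with positive slope.
#'
#' @param matrix a [protein_matrix()] with `scale_tag` `"log2-imputed"`, or
#'   `"log2"` if it contains no missing values.
#' @return The matrix with `scale_tag = "zscored"`.
#' @export
zscore_within_sample <- function(matrix) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (matrix$scale_tag == "log2" && anyNA(matrix$values))
    stop("matrix has missing values; impute before z-scoring")
  matrix <- advance_scale(matrix, c("log2", "log2-imputed"), "zscored")
  mu <- colMeans(matrix$values)
  sd_ <- apply(matrix$values, 2, stats::sd)
  if (any(sd_ == 0))
    stop("zero-variance sample: ", sample_ids(matrix)[which(sd_ == 0)[1]])
  matrix$values <- sweep(sweep(matrix$values, 2, mu, "-"), 2, sd_, "/")
  matrix
}

#' Restrict two matrices to their shared proteins
#'
#' Both matrices are subset to the intersection of their protein ids, sorted
#' identically, so a model trained on one can be applied to the other. Gene
#' symbols are matched exactly (case-sensitive); Perseus-style multi-id
#' strings ("A;B;C") are first reduced to their leading symbol when both
#' matrices carry them.
#'
#' @param a,b [protein_matrix()] objects.
#' @return A list with elements `a` and `b`, each restricted to the shared
#'   proteins in sorted order.
#' @export
intersect_features <- function(a, b) {
  stopifnot(inherits(a, "protein_matrix"), inherits(b, "protein_matrix"))
  strip <- function(x) sub(";.*$", "", x)
  multi_a <- any(grepl(";", protein_ids(a)))
  multi_b <- any(grepl(";", protein_ids(b)))
  ia <- protein_ids(a); ib <- protein_ids(b)
  if (multi_a && multi_b) { ia <- strip(ia); ib <- strip(ib) }
  shared <- sort(intersect(ia, ib))
  if (length(shared) == 0) stop("no shared proteins between the two matrices")
  a <- subset_proteins(a, match(shared, ia))
  b <- subset_proteins(b, match(shared, ib))
  rownames(a$values) <- shared
  rownames(b$values) <- shared
  list(a = a, b = b)
}
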