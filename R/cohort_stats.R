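#' Volcano / SAM-style test parameters
#'
#' @param s0 variance-stabilization constant added to the t-statistic
#'   denominator (default 0.1); `s0 = 0` reduces the statistic to the
#'   ordinary pooled-variance two-sample t.
#' @param fdr target permutation FDR (default 0.05).
#' @param n_perm number of group-label permutations (default 250).
#' @param seed integer seed for the permutations.
#' @param welch use the Welch (unpooled) denominator instead of the pooled
#'   one (default `FALSE`, matching the SAM/Perseus convention).
#' @param perm_summary how permutation exceedance counts are summarized into
#'   the FDR numerator: `"mean"` (default; the standard permutation-FDR
#'   estimator, stable at extreme cutoffs where a median of small counts
#'   degenerates to zero and would spuriously call the single most extreme
#'   protein) or `"median"` (the SAM summary).
#' @return list of class `volcano_params`.
#' @export
volcano_params <- function(s0 = 0.1, fdr = 0.05, n_perm = 250L, seed = 1L,
                           welch = FALSE, perm_summary = c("mean", "median")) {
  stopifnot(s0 >= 0, fdr > 0, fdr < 1, n_perm >= 10)
  perm_summary <- match.arg(perm_summary)
  structure(list(s0 = s0, fdr = fdr, n_perm = as.integer(n_perm),
                 seed = as.integer(seed), welch = welch,
                 perm_summary = perm_summary),
            class = "volcano_params")
}

# moderated two-sample statistic per row of a values matrix
s0_tstat <- function(vals, ia, ib, s0, welch = FALSE) {
  na <- length(ia); nb <- length(ib)
  ma <- rowMeans(vals[, ia, drop = FALSE])
  mb <- rowMeans(vals[, ib, drop = FALSE])
  va <- rowSums((vals[, ia, drop = FALSE] - ma)^2) / (na - 1)
  vb <- rowSums((vals[, ib, drop = FALSE] - mb)^2) / (nb - 1)
  if (welch) {
    se <- sqrt(va / na + vb / nb)
  } else {
    sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
    se <- sp * sqrt(1 / na + 1 / nb)
  }
  list(diff = ma - mb, t = (ma - mb) / (se + s0))
}

#' S0-moderated permutation-FDR differential test (volcano)
#'
#' Per protein computes the moderated statistic
#' `t_s0 = (mean_A - mean_B) / (s_pooled * sqrt(1/n_A + 1/n_B) + s0)` and
#' calls a protein significant when it exceeds the smallest symmetric
#' cutoff on `|t_s0|` whose estimated FDR is at or below the target. The
#' FDR at a cutoff is estimated from group-label permutations as the median
#' permutation exceedance count divided by the observed exceedance count
#' (the SAM construction that Perseus's volcano curve parameterizes by
#' `(FDR, S0)`).
#'
#' @param matrix an imputed [protein_matrix()].
#' @param groupA,groupB disjoint character vectors of sample ids, each of
#'   size >= 2.
#' @param params a [volcano_params()].
#' @return data.frame of class `volcano_result`: `protein`, `diff`
#'   (mean_A - mean_B), `t_s0`, `significant`; attributes `cutoff`,
#'   `est_fdr`, `params`, `n_A`, `n_B`.
#' @export
sam_test <- function(matrix, groupA, groupB, params = volcano_params()) {
  stopifnot(inherits(matrix, "protein_matrix"), inherits(params, "volcano_params"))
  if (length(intersect(groupA, groupB)) > 0) stop("groups overlap")
  if (length(groupA) < 2 || length(groupB) < 2) stop("each group needs >= 2 samples")
  ids <- sample_ids(matrix)
  if (!all(c(groupA, groupB) %in% ids)) stop("unknown sample ids")
  if (anyNA(matrix$values[, c(groupA, groupB)]))
    stop("matrix has missing values; impute first")
  n_distinct <- choose(length(groupA) + length(groupB), length(groupA))
  if (params$n_perm > n_distinct)
    warning("n_perm exceeds the number of distinct label permutations; FDR resolution limited")

  vals <- matrix$values
  ia <- match(groupA, ids); ib <- match(groupB, ids)
  obs <- s0_tstat(vals, ia, ib, params$s0, params$welch)
  at <- abs(obs$t)
  at[!is.finite(at)] <- 0   # zero difference over zero spread: never called

  both <- c(ia, ib)
  na <- length(ia)
  set.seed(params$seed)
  # candidate cutoffs: the observed |t| values, scanned from the least
  # extreme up; exceedance counts per permutation are found by binary search
  # on the sorted permuted |t|
  cand <- sort(unique(at))
  perm_counts <- matrix(0L, params$n_perm, length(cand))
  for (r in seq_len(params$n_perm)) {
    sh <- sample(both)
    pt <- abs(s0_tstat(vals, sh[seq_len(na)], sh[-seq_len(na)],
                       params$s0, params$welch)$t)
    pt <- sort(pt[is.finite(pt)])
    # exceedances of each candidate cutoff (>=)
    perm_counts[r, ] <- length(pt) - findInterval(cand, pt, left.open = TRUE)
  }
  med_perm <- if (params$perm_summary == "median")
    apply(perm_counts, 2, stats::median) else colMeans(perm_counts)
  n_obs <- length(at) - findInterval(cand, sort(at), left.open = TRUE)
  est_fdr <- ifelse(n_obs > 0, pmin(1, med_perm / n_obs), 0)
  ok <- which(est_fdr <= params$fdr)
  if (length(ok) > 0) {
    cutoff <- cand[min(ok)]
    significant <- at >= cutoff
    fdr_at_cut <- est_fdr[min(ok)]
  } else {
    cutoff <- Inf
    significant <- rep(FALSE, length(at))
    fdr_at_cut <- NA_real_
  }
  out <- data.frame(protein = protein_ids(matrix), diff = obs$diff,
                    t_s0 = obs$t, significant = significant,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "cutoff") <- cutoff
  attr(out, "est_fdr") <- fdr_at_cut
  attr(out, "n_A") <- length(groupA)
  attr(out, "n_B") <- length(groupB)
  attr(out, "params") <- params
  class(out) <- c("volcano_result", "data.frame")
  out
}

#' Volcano plot of a differential test
#'
#' @param result a [sam_test()] result.
#' @return a ggplot object (difference vs `|t_s0|`-derived score, significant
#'   proteins highlighted).
#' @export
plot_volcano <- function(result) {
  stopifnot(inherits(result, "volcano_result"))
  ggplot2::ggplot(result, ggplot2::aes(x = diff, y = abs(t_s0),
                                       colour = significant)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60", `TRUE` = "firebrick")) +
    ggplot2::labs(x = "difference (A - B)", y = "|t_s0|") +
    ggplot2::theme_minimal()
}

#' One-tailed marker contrasts with Benjamini-Hochberg correction
#'
#' Per protein, a one-tailed Welch t-test of group A against group B in the
#' stated direction; q-values are BH-adjusted over all tested proteins. The
#' direction is a required argument and is never inferred from the data.
#'
#' @param matrix an imputed [protein_matrix()].
#' @param groupA,groupB disjoint sample-id sets, each >= 2.
#' @param direction `"greater"` (A > B) or `"less"`.
#' @return data.frame: `protein`, `diff`, `t`, `p`, `q`.
#' @export
marker_contrast <- function(matrix, groupA, groupB,
                            direction = c("greater", "less")) {
  direction <- match.arg(direction)
  stopifnot(inherits(matrix, "protein_matrix"))
  if (length(intersect(groupA, groupB)) > 0) stop("groups overlap")
  if (length(groupA) < 2 || length(groupB) < 2) stop("each group needs >= 2 samples")
  ids <- sample_ids(matrix)
  if (!all(c(groupA, groupB) %in% ids)) stop("unknown sample ids")
  A <- matrix$values[, groupA, drop = FALSE]
  B <- matrix$values[, groupB, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- rowSums((A - ma)^2) / (na - 1)
  vb <- rowSums((B - mb)^2) / (nb - 1)
  se2 <- va / na + vb / nb
  tt <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  p <- if (direction == "greater") stats::pt(tt, df, lower.tail = FALSE)
       else stats::pt(tt, df, lower.tail = TRUE)
  degenerate <- se2 == 0
  if (any(degenerate)) {
    # zero variance in both groups: p = 1/2 at zero difference (continuity
    # decision), 0/1 by sign otherwise
    d <- ma - mb
    s <- if (direction == "greater") d else -d
    p[degenerate] <- ifelse(s[degenerate] > 0, 0, ifelse(s[degenerate] < 0, 1, 0.5))
    message(sum(degenerate), " proteins with zero variance in both groups; p set by sign (0.5 at zero difference)")
  }
  data.frame(protein = protein_ids(matrix), diff = ma - mb, t = tt, p = p,
             q = stats::p.adjust(p, method = "BH"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Chi-squared enrichment of dominant niches across subtypes
#'
#' Builds the observed subtype x dominant-niche contingency table, the
#' expected table under independence (row x column margins / total), and the
#' Pearson chi-squared statistic with `(r-1)(c-1)` degrees of freedom. With
#' a `focus` pair, the table is additionally collapsed to 2 x 2 (focus
#' subtype vs rest, focus niche vs rest) with its own chi-squared and
#' p-value.
#'
#' @param dominant named vector: sample id -> dominant niche label.
#' @param subtype named vector: sample id -> subtype.
#' @param focus optional `c(subtype, niche)` pair for the 2 x 2 collapse,
#'   e.g. `c("proneural", "IT")`.
#' @param yates apply the Yates continuity correction (2 x 2 collapse only;
#'   default `FALSE`, matching a plain Pearson test).
#' @return list of class `enrichment_table`: `observed`, `expected`, `chi2`,
#'   `df`, `p_value`, and (with `focus`) `focus_table`, `focus_chi2`,
#'   `focus_p`.
#' @export
chi_squared_niche_enrichment <- function(dominant, subtype, focus = NULL,
                                         yates = FALSE) {
  ids <- names(dominant)
  if (is.null(ids) || !all(ids %in% names(subtype)))
    stop("every sample needs both a dominant-niche and a subtype label")
  sub <- subtype[ids]
  obs <- table(subtype = factor(sub), niche = factor(dominant, NICHE_LEVELS))
  obs <- obs[rowSums(obs) > 0, colSums(obs) > 0, drop = FALSE]
  res <- pearson_chi2(unclass(obs), yates = FALSE)
  out <- list(observed = unclass(obs), expected = res$expected,
              chi2 = res$chi2, df = res$df, p_value = res$p)
  if (!is.null(focus)) {
    stopifnot(length(focus) == 2)
    f2 <- matrix(c(sum(sub == focus[1] & dominant == focus[2]),
                   sum(sub == focus[1] & dominant != focus[2]),
                   sum(sub != focus[1] & dominant == focus[2]),
                   sum(sub != focus[1] & dominant != focus[2])),
                 2, 2, byrow = TRUE,
                 dimnames = list(c(focus[1], "other"),
                                 c(focus[2], "other")))
    fres <- pearson_chi2(f2, yates = yates)
    out$focus_table <- f2
    out$focus_chi2 <- fres$chi2
    out$focus_p <- fres$p
  }
  if (any(res$expected < 1))
    warning("expected cell count < 1; consider collapsing categories or an exact test")
  structure(out, class = "enrichment_table")
}

# Pearson chi-squared on a contingency matrix; closed form sum (O-E)^2 / E
pearson_chi2 <- function(O, yates = FALSE) {
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  d <- abs(O - E)
  if (yates && all(dim(O) == 2)) d <- pmax(0, d - 0.5)
  chi2 <- sum(d^2 / E)
  df <- (nrow(O) - 1) * (ncol(O) - 1)
  list(chi2 = chi2, df = df, expected = E,
       p = stats::pchisq(chi2, df, lower.tail = FALSE))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("chi-squared = %.4f, df = %d, p = %.4g\n", x$chi2, x$df, x$p_value))
  if (!is.null(x$focus_chi2))
    cat(sprintf("focus 2x2: chi-squared = %.4f, p = %.4g\n", x$focus_chi2, x$focus_p))
  invisible(x)
}

#' PCA embedding of samples
#'
#' Samples are observations, proteins features, mean-centered per protein
#' (no scaling). Component signs follow a deterministic convention: the
#' protein loading with the largest absolute value is positive.
#'
#' @param matrix an imputed [protein_matrix()].
#' @param n_components number of components (default 2).
#' @return list: `scores` (sample x component), `explained` (variance
#'   fractions), `loadings`.
#' @export
pca_embedding <- function(matrix, n_components = 2L) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (anyNA(matrix$values)) stop("matrix has missing values; impute first")
  n <- ncol(matrix$values); p <- nrow(matrix$values)
  if (n_components > min(n, p))
    stop("more components than min(n_samples, n_proteins)")
  pc <- stats::prcomp(t(matrix$values), center = TRUE, scale. = FALSE)
  k <- seq_len(n_components)
  load <- pc$rotation[, k, drop = FALSE]
  flip <- vapply(k, function(j) {
    i <- which.max(abs(load[, j]))
    if (load[i, j] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, k, drop = FALSE], 2, flip, "*")
  load <- sweep(load, 2, flip, "*")
  expl <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, explained = expl[k], loadings = load)
}

#' Pearson-correlation average-linkage clustering of samples
#'
#' Sample-sample distance is `1 - Pearson r` over all proteins; the tree is
#' built with average linkage (UPGMA).
#'
#' @param matrix an imputed [protein_matrix()].
#' @param annotations optional data.frame of per-sample tracks (e.g. subtype,
#'   dominant niche), carried through for plotting.
#' @return list: `hclust` (stats::hclust object), `order` (leaf sample ids),
#'   `dist` (the distance matrix), `annotations`.
#' @export
pearson_hierarchical_clustering <- function(matrix, annotations = NULL) {
  stopifnot(inherits(matrix, "protein_matrix"))
  if (anyNA(matrix$values)) stop("matrix has missing values; impute first")
  sds <- apply(matrix$values, 2, stats::sd)
  if (any(sds == 0))
    stop("constant sample column (correlation undefined): ",
         sample_ids(matrix)[which(sds == 0)[1]])
  d <- 1 - stats::cor(matrix$values)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  list(hclust = hc, order = sample_ids(matrix)[hc$order], dist = d,
       annotations = annotations)
}

#' Spearman correlation of group-averaged profiles between two matrices
#'
#' For each group, proteins are averaged across the group's samples in each
#' matrix and the two averaged vectors are rank-correlated (average ranks
#' for ties). The matrices must already share a feature set
#' (see [intersect_features()]).
#'
#' @param a,b feature-intersected [protein_matrix()] objects.
#' @param groups named vector: sample id -> group, covering samples of both
#'   matrices.
#' @return named numeric vector of Spearman rho per group.
#' @export
spearman_group_correlation <- function(a, b, groups) {
  stopifnot(inherits(a, "protein_matrix"), inherits(b, "protein_matrix"))
  if (!identical(protein_ids(a), protein_ids(b)))
    stop("matrices are not feature-intersected; run intersect_features first")
  gl <- sort(unique(as.character(groups)))
  vapply(gl, function(g) {
    sa <- intersect(sample_ids(a), names(groups)[groups == g])
    sb <- intersect(sample_ids(b), names(groups)[groups == g])
    if (length(sa) == 0 || length(sb) == 0)
      stop("group '", g, "' absent from one of the matrices")
    va <- rowMeans(a$values[, sa, drop = FALSE])
    vb <- rowMeans(b$values[, sb, drop = FALSE])
    stats::cor(va, vb, method = "spearman")
  }, numeric(1))
}
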