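# hand fixture: two groups of three samples, values chosen for closed-form
# checks of the moderated statistic
fixture_two_group <- function() {
  v <- rbind(p1 = c(10, 11, 12, 8, 9, 10),
             p2 = c(5, 5.5, 6, 5, 5.5, 6),
             p3 = c(3, 3, 3, 3, 3, 3))
  colnames(v) <- paste0("s", 1:6)
  toy_matrix(v, scale_tag = "log2-imputed")
}

test_that("at s0 = 0 the moderated statistic is the textbook pooled t", {
  m <- fixture_two_group()
  A <- paste0("s", 1:3); B <- paste0("s", 4:6)
  res <- suppressWarnings(sam_test(m, A, B, volcano_params(s0 = 0, n_perm = 10, seed = 1)))
  for (i in 1:2) {
    a <- m$values[i, A]; b <- m$values[i, B]
    sp <- sqrt(((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
                 (length(a) + length(b) - 2))
    t_ref <- (mean(a) - mean(b)) / (sp * sqrt(1 / 3 + 1 / 3))
    expect_equal(res$t_s0[i], t_ref, tolerance = 1e-12)
    expect_equal(res$diff[i], mean(a) - mean(b), tolerance = 1e-12)
  }
  # s0 > 0 shrinks nonzero statistics toward zero and leaves zero at zero
  res2 <- suppressWarnings(sam_test(m, A, B, volcano_params(s0 = 0.5, n_perm = 10, seed = 1)))
  expect_lt(abs(res2$t_s0[1]), abs(res$t_s0[1]))
  expect_equal(res2$t_s0[2], 0)
  expect_error(sam_test(m, A, c("s3", "s4")), "overlap")
})

test_that("null data yield few significant calls across seeds", {
  # fully null: both groups from one distribution; median significant
  # count over seeds should be 0 and each run stays below the binomial bound
  m_prot <- 2000
  counts <- vapply(1:8, function(seed) {
    set.seed(seed + 100)
    v <- matrix(rnorm(m_prot * 20, 20, 1), m_prot, 20,
                dimnames = list(sprintf("p%05d", 1:m_prot), paste0("s", 1:20)))
    m <- toy_matrix(v, scale_tag = "log2-imputed")
    res <- sam_test(m, paste0("s", 1:10), paste0("s", 11:20),
                    volcano_params(s0 = 0.1, fdr = 0.05, n_perm = 60,
                                   seed = seed))
    sum(res$significant)
  }, numeric(1))
  expect_equal(median(counts), 0)
  expect_true(all(counts <= 0.05 * m_prot + 3 * sqrt(0.05 * m_prot)))
})

test_that("spiked proteins are recovered by the volcano at FDR 0.05", {
  cfg <- small_config(n_proteins = 1500, n_signature_per_niche = 0,
                      missing_censor_quantile = 0, n_bulk = 40,
                      subtype_coupling = list(), seed = 17)
  bulk <- generate_bulk_cohort(generate_reference_atlas(cfg), cfg)
  m <- bulk$matrix
  groupA <- colnames(m$values)[1:20]
  groupB <- colnames(m$values)[21:40]
  spiked <- rownames(m$values)[sample(1500, 50)]
  m <- spike_differential(m, groupA, spiked, delta = 2)
  m$scale_tag <- "log2-imputed"
  res <- sam_test(m, groupA, groupB,
                  volcano_params(s0 = 0.1, fdr = 0.05, n_perm = 100, seed = 2))
  hits <- res$protein[res$significant]
  expect_gte(mean(spiked %in% hits), 0.8)
  # false hits stay within the FDR budget (with simulation slack)
  if (length(hits) > 0)
    expect_lte(mean(!hits %in% spiked), 0.15)
  p <- plot_volcano(res)
  expect_s3_class(p, "ggplot")
})

test_that("one-tailed marker contrast gives null p near 0.5 and correct BH q-values", {
  set.seed(3)
  v <- matrix(rnorm(100 * 12, 20, 1), 100, 12,
              dimnames = list(sprintf("p%03d", 1:100), paste0("s", 1:12)))
  m <- toy_matrix(v, scale_tag = "log2-imputed")
  res <- marker_contrast(m, paste0("s", 1:6), paste0("s", 7:12), "greater")
  expect_equal(mean(res$p), 0.5, tolerance = 0.1)
  expect_gte(min(res$q), 0.2)
  # BH: q at rank k is p_(k) * m / k before monotonization
  p_known <- c(rep(1e-6, 10), seq(0.1, 0.99, length.out = 90))
  q <- p.adjust(p_known, "BH")
  expect_equal(q[10], 1e-6 * 100 / 10, tolerance = 1e-15)
  # BH is invariant to input order and monotone after sorting
  perm <- sample(100)
  expect_equal(p.adjust(p_known[perm], "BH")[order(perm)], q)
  expect_true(all(diff(sort(q)) >= 0))
})

test_that("marker contrast detects a one-sided shift and respects direction", {
  set.seed(5)
  v <- matrix(rnorm(50 * 12, 20, 0.5), 50, 12,
              dimnames = list(sprintf("p%03d", 1:50), paste0("s", 1:12)))
  v[1:10, 1:6] <- v[1:10, 1:6] + 2
  m <- toy_matrix(v, scale_tag = "log2-imputed")
  up <- marker_contrast(m, paste0("s", 1:6), paste0("s", 7:12), "greater")
  expect_true(all(up$q[1:10] < 0.05))
  down <- marker_contrast(m, paste0("s", 1:6), paste0("s", 7:12), "less")
  expect_true(all(down$p[1:10] > 0.95))
})

test_that("chi-squared matches the closed form on hand fixtures", {
  dominant <- setNames(c(rep("IT", 10), rep("CT", 5), rep("IT", 2), rep("CT", 13)),
                       paste0("s", 1:30))
  subtype <- setNames(c(rep("proneural", 15), rep("mesenchymal", 15)),
                      paste0("s", 1:30))
  enr <- chi_squared_niche_enrichment(dominant, subtype,
                                      focus = c("proneural", "IT"))
  O <- matrix(c(10, 5, 2, 13), 2, 2, byrow = TRUE)
  E <- outer(rowSums(O), colSums(O)) / sum(O)
  expect_equal(enr$focus_chi2, sum((O - E)^2 / E), tolerance = 1e-9)
  expect_equal(enr$focus_p, pchisq(sum((O - E)^2 / E), 1, lower.tail = FALSE),
               tolerance = 1e-12)
  expect_equal(unname(rowSums(enr$expected)), unname(rowSums(enr$observed)),
               tolerance = 1e-9)
  expect_equal(unname(colSums(enr$expected)), unname(colSums(enr$observed)),
               tolerance = 1e-9)
  # agrees with stats::chisq.test without continuity correction
  ref <- suppressWarnings(chisq.test(O, correct = FALSE))
  expect_equal(enr$focus_chi2, unname(ref$statistic), tolerance = 1e-9)
  # observed == expected gives chi2 = 0, p = 1
  bal_dom <- setNames(rep(c("IT", "CT"), 10), paste0("b", 1:20))
  bal_sub <- setNames(rep(c("proneural", "proneural", "mesenchymal", "mesenchymal"), 5),
                      paste0("b", 1:20))
  bal <- chi_squared_niche_enrichment(bal_dom, bal_sub)
  expect_equal(bal$chi2, 0, tolerance = 1e-12)
  expect_equal(bal$p_value, 1, tolerance = 1e-12)
})

test_that("a 3x5 table agrees with stats::chisq.test to 1e-9", {
  set.seed(8)
  dominant <- setNames(sample(NICHE_LEVELS, 200, replace = TRUE,
                              prob = c(.3, .25, .2, .15, .1)), paste0("s", 1:200))
  subtype <- setNames(sample(c("proneural", "classical", "mesenchymal"), 200,
                             replace = TRUE), paste0("s", 1:200))
  enr <- chi_squared_niche_enrichment(dominant, subtype)
  ref <- suppressWarnings(chisq.test(table(subtype, factor(dominant, NICHE_LEVELS)),
                                     correct = FALSE))
  expect_equal(enr$chi2, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(enr$df, unname(ref$parameter))
  expect_equal(enr$p_value, ref$p.value, tolerance = 1e-9)
})

test_that("coupled cohorts reject and uncoupled cohorts calibrate the focus test", {
  cfg_on <- small_config(n_bulk = 110, seed = 1)
  atlas <- generate_reference_atlas(cfg_on)
  p_on <- vapply(1:30, function(r) {
    bulk <- generate_bulk_cohort(atlas, cfg_on, seed = 1000 + r)
    dom <- setNames(true_dominant(bulk), rownames(bulk$true_weights))
    suppressWarnings(
      chi_squared_niche_enrichment(dom, bulk$subtype_of_sample,
                                   focus = c("proneural", "IT"))$focus_p)
  }, numeric(1))
  expect_gte(mean(p_on < 0.05), 0.95)
  cfg_off <- small_config(n_bulk = 110, subtype_coupling = list(), seed = 1)
  p_off <- vapply(1:30, function(r) {
    bulk <- generate_bulk_cohort(atlas, cfg_off, seed = 2000 + r)
    dom <- setNames(true_dominant(bulk), rownames(bulk$true_weights))
    suppressWarnings(
      chi_squared_niche_enrichment(dom, bulk$subtype_of_sample,
                                   focus = c("proneural", "IT"))$focus_p)
  }, numeric(1))
  expect_lte(mean(p_off < 0.05), 0.25)
})

test_that("PCA separates two point clusters on PC1 with matching variance share", {
  set.seed(2)
  n <- 20
  v <- matrix(rnorm(50 * n, 0, 0.01), 50, n,
              dimnames = list(paste0("p", 1:50), paste0("s", 1:n)))
  v[1:10, 1:10] <- v[1:10, 1:10] + 5   # half the samples shifted on 10 proteins
  m <- toy_matrix(v, scale_tag = "log2-imputed")
  emb <- pca_embedding(m, 2)
  pc1 <- emb$scores[, 1]
  expect_true(max(pc1[1:10]) < min(pc1[11:n]) ||
                min(pc1[1:10]) > max(pc1[11:n]))
  # PC1's variance share equals the between-cluster share of total scatter
  S <- t(v)
  mm <- colMeans(S)
  g1 <- colMeans(S[1:10, ]); g2 <- colMeans(S[11:n, ])
  between <- 10 * sum((g1 - mm)^2) + 10 * sum((g2 - mm)^2)
  total <- sum(sweep(S, 2, mm)^2)
  expect_equal(emb$explained[1], between / total, tolerance = 0.01)
  expect_lte(sum(emb$explained), 1)
  # duplicated sample gets identical scores
  v2 <- cbind(v, s_dup = v[, 1])
  emb2 <- pca_embedding(toy_matrix(v2, scale_tag = "log2-imputed"), 2)
  expect_equal(unname(emb2$scores["s_dup", ]), unname(emb2$scores["s1", ]),
               tolerance = 1e-9)
  expect_error(pca_embedding(m, 60), "components")
})

test_that("average-linkage heights on three samples match the hand computation", {
  # construct three samples with known pairwise Pearson correlations
  set.seed(4)
  base <- rnorm(200)
  v <- cbind(s1 = base,
             s2 = base + rnorm(200, 0, 0.3),
             s3 = -base + rnorm(200, 0, 0.5))
  rownames(v) <- paste0("p", 1:200)
  m <- toy_matrix(v, scale_tag = "log2-imputed")
  cl <- pearson_hierarchical_clustering(m)
  d <- 1 - cor(v)
  expect_equal(cl$dist, d, tolerance = 1e-12)
  expect_true(isSymmetric(d))
  expect_equal(unname(diag(d)), rep(0, 3), tolerance = 1e-12)
  # s1, s2 merge first at d12; then the average of d13 and d23
  h <- sort(c(d["s1", "s2"], mean(c(d["s1", "s3"], d["s2", "s3"]))))
  expect_equal(cl$hclust$height, h, tolerance = 1e-9)
  # identical samples: distance 0, merged first
  v2 <- cbind(v, s4 = v[, "s1"])
  cl2 <- pearson_hierarchical_clustering(toy_matrix(v2, scale_tag = "log2-imputed"))
  expect_equal(cl2$hclust$height[1], 0, tolerance = 1e-12)
  expect_error(pearson_hierarchical_clustering(
    toy_matrix(cbind(v, s5 = rep(1, 200)), scale_tag = "log2-imputed")),
    "constant")
})

test_that("spearman group correlation handles monotone transforms and ties", {
  ids <- sprintf("p%02d", 1:10)
  va <- matrix(c(1:10, 2:11), 10, 2, dimnames = list(ids, c("x1", "x2")))
  # b is a monotone transform of a's group mean -> rho = 1
  vb <- matrix(exp((1:10) / 3), 10, 1, dimnames = list(ids, "y1"))
  a <- toy_matrix(va, scale_tag = "log2-imputed")
  b <- toy_matrix(vb, scale_tag = "log2-imputed")
  groups <- setNames(rep("g", 3), c("x1", "x2", "y1"))
  expect_equal(unname(spearman_group_correlation(a, b, groups)), 1)
  # reversed ranks -> rho = -1
  vb2 <- matrix(10:1, 10, 1, dimnames = list(ids, "y1"))
  b2 <- toy_matrix(vb2, scale_tag = "log2-imputed")
  expect_equal(unname(spearman_group_correlation(a, b2, groups)), -1)
  # ties: compare against the average-rank Pearson formula
  va3 <- matrix(c(1, 1, 2, 3, 4, 4, 5, 6, 7, 8), 10, 1,
                dimnames = list(ids, "x1"))
  vb3 <- matrix(c(2, 1, 3, 3, 5, 6, 6, 7, 9, 9), 10, 1,
                dimnames = list(ids, "y1"))
  a3 <- toy_matrix(va3, scale_tag = "log2-imputed")
  b3 <- toy_matrix(vb3, scale_tag = "log2-imputed")
  groups3 <- setNames(rep("g", 2), c("x1", "y1"))
  rho_hand <- cor(rank(va3[, 1]), rank(vb3[, 1]))
  expect_equal(unname(spearman_group_correlation(a3, b3, groups3)), rho_hand,
               tolerance = 1e-12)
  expect_error(spearman_group_correlation(a3, b3, setNames("g2", "x9")), "absent")
})
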