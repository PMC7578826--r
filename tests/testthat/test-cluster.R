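# Case-only subtype discovery: K-means, silhouette k-selection,
# differential expression, clinical associations, and the extreme-value
# permutation test.

# two case groups separated by d log2 units on the first `shifted` proteins
two_blob_cases <- function(seed, n1 = 7, n2 = 16, d = 6, p = 10,
                           shifted = 4) {
  set.seed(seed)
  m <- matrix(rnorm((n1 + n2) * p), n1 + n2)
  m[(n1 + 1):(n1 + n2), 1:shifted] <-
    m[(n1 + 1):(n1 + n2), 1:shifted] + d
  dimnames(m) <- list(sprintf("case%02d", 1:(n1 + n2)), sprintf("P%02d", 1:p))
  2^m
}

test_that("k-means recovers point masses exactly with zero WCSS", {
  m <- 2^rbind(matrix(1, 5, 4), matrix(8, 9, 4))
  dimnames(m) <- list(sprintf("c%02d", 1:14), sprintf("P%d", 1:4))
  cl <- kmeans_cluster(m, 2, seed = 1)
  expect_equal(cl$tot_withinss, 0)
  expect_equal(cl$sizes, c(5L, 9L))                 # cluster 1 is smaller
  expect_equal(unname(cl$assignments), rep(c(1L, 2L), c(5, 9)))
})

test_that("k-means is invariant to sample order up to the identical partition", {
  m <- two_blob_cases(3)
  cl <- kmeans_cluster(m, 2, seed = 7)
  perm <- sample(nrow(m))
  cl2 <- kmeans_cluster(m[perm, ], 2, seed = 7)
  expect_equal(cl2$assignments[names(cl$assignments)], cl$assignments)
})

test_that("a 7-vs-16 split with strong markers is recovered", {
  m <- two_blob_cases(11)
  cl <- kmeans_cluster(m, 2, seed = 2)
  expect_equal(cl$sizes, c(7L, 16L))
  expect_true(all(cl$assignments[1:7] == 1L))
})

test_that("silhouette selection finds k = 2 for two tight groups", {
  m <- two_blob_cases(5, d = 10, shifted = 10)
  ck <- choose_k(m, k_range = 2:5, seed = 3)
  expect_equal(ck$chosen_k, 2L)
  expect_gt(max(ck$silhouette_by_k), 0.5)
  expect_error(choose_k(m, k_range = 1:3), "k_range")
})

test_that("a single Gaussian blob never shows strong silhouette structure", {
  set.seed(17)
  m <- 2^matrix(rnorm(30 * 8), 30,
                dimnames = list(sprintf("c%02d", 1:30), sprintf("P%d", 1:8)))
  ck <- choose_k(m, k_range = 2:5, seed = 4)
  expect_lt(max(ck$silhouette_by_k), 0.3)
})

test_that("planted subtypes are recovered with high adjusted Rand index", {
  # Monte-Carlo over 20 cohorts at a 2-log2-unit marker contrast: the
  # average agreement with the planted subtypes stays at or above 0.8
  aris <- vapply(1:20, function(s) {
    coh <- generate_cohort(small_config(seed = 8000 + s,
                                        n_subtype_markers = 8,
                                        subtype_effect = 2))
    cases <- coh$abundance[coh$metadata$label == "case", ]
    sel <- c(coh$truth$subtype_markers,
             setdiff(colnames(cases),
                     c(coh$truth$signal_proteins,
                       coh$truth$subtype_markers))[1:8])
    cl <- kmeans_cluster(cases[, sel], 2, seed = s)
    ari(cl$assignments, coh$truth$subtype_labels[rownames(cases)])
  }, 0)
  expect_gte(mean(aris), 0.8)
  expect_gt(min(aris), 0)     # never anti-correlated with the truth
})

test_that("differential expression applies the uncapped correction", {
  # strong subtype contrast so marker detection is decisive
  coh <- generate_cohort(small_config(seed = 71, subtype_effect = 3))
  cases <- coh$abundance[coh$metadata$label == "case", ]
  truth <- coh$truth$subtype_labels[rownames(cases)]
  sel <- c(coh$truth$subtype_markers,
           setdiff(colnames(cases), coh$truth$subtype_markers)[1:10])
  de <- differential_expression(cases[, sel], truth)
  expect_equal(de$bonferroni_p, de$raw_p * length(sel))
  expect_false(is.unsorted(de$raw_p))
  # planted markers reach corrected significance
  mk <- de[de$protein %in% coh$truth$subtype_markers, ]
  expect_true(all(mk$bonferroni_p < 0.05))
  expect_true(all(mk$higher_cluster == 2L))
  # relabelling the clusters flips the direction but not the p-values
  de_flip <- differential_expression(cases[, sel], 3L - truth)
  expect_equal(de_flip$raw_p, de$raw_p)
  expect_equal(de_flip$higher_cluster, 3L - de$higher_cluster)
  # a protein identical across clusters is non-significant
  cm <- cases[, sel]
  cm[, 1] <- rep(c(2, 4), length.out = nrow(cm))
  de2 <- differential_expression(cm, truth)
  expect_gt(de2$raw_p[de2$protein == colnames(cm)[1]], 0.5)
})

test_that("the full subtype fit ties the pieces together", {
  coh <- generate_cohort(small_config(seed = 72, n_subtype_markers = 10,
                                      subtype_effect = 3))
  cases <- coh$abundance[coh$metadata$label == "case", ]
  sel <- c(coh$truth$subtype_markers,
           setdiff(colnames(cases),
                   c(coh$truth$signal_proteins,
                     coh$truth$subtype_markers))[1:6])
  fit <- cluster_subtypes(cases, candidates = sel, seed = 9)
  expect_s3_class(fit, "subtype_fit")
  expect_equal(fit$chosen_k,
               as.integer(names(which.max(fit$silhouette_by_k))))
  expect_equal(sum(fit$cluster_sizes), nrow(cases))
  expect_true(all(fit$cluster_sizes > 0))
  expect_equal(sort(unique(fit$assignments)), seq_len(fit$chosen_k))
  expect_equal(ncol(fit$pca), 3L)
})

test_that("clinical association reports medians, chi-square and Fisher", {
  coh <- generate_cohort(small_config(seed = 73))
  md <- coh$metadata[coh$metadata$label == "case", ]
  truth <- coh$truth$subtype_labels[md$sample_id]
  assoc <- clinical_association(
    md, truth,
    continuous = c("delivery_week", "protein_24h"),
    binary = c("creatinine_high", "sodium_low"))
  expect_equal(nrow(assoc$continuous), 2L)
  expect_equal(assoc$continuous$bonferroni_p, assoc$continuous$raw_p * 2)
  expect_equal(assoc$binary$evaluable_cluster1 +
               assoc$binary$evaluable_cluster2,
               rep(nrow(md), 2))
  # identical distributions give p near 1 (groups interleaved so each
  # cluster sees the same value mix)
  md2 <- md
  md2$flat <- rep(c(0, 1), length.out = nrow(md))
  md2$flatc <- rep(c(1.2, 3.4), length.out = nrow(md))
  a2 <- clinical_association(md2, rep(c(1L, 1L, 2L, 2L),
                                      length.out = nrow(md2)),
                             continuous = "flatc", binary = "flat")
  expect_gt(a2$continuous$raw_p, 0.5)
  expect_gt(a2$binary$fisher_p, 0.5)
  # variables without evaluable subjects are excluded with a reason
  md3 <- md
  md3$gone <- NA_real_
  a3 <- clinical_association(md3, truth, continuous = "gone")
  expect_equal(a3$excluded$variable, "gone")
})

test_that("a fully concordant derangement table reproduces the exact test", {
  # 0/7 vs 8/15 evaluable: the creatinine-style table
  t22 <- matrix(c(0, 8, 7, 7), 2)
  expect_equal(round(fisher_exact_2x2(t22)$p_value, 2), 0.02)
  md <- data.frame(ind = c(rep(0, 7), rep(1, 8), rep(0, 7), NA))
  grp <- rep(c(1L, 2L), c(7, 16))
  assoc <- clinical_association(md, grp, binary = "ind")
  expect_equal(assoc$binary$n1_cluster2, 8)
  expect_equal(assoc$binary$evaluable_cluster2, 15)
  expect_equal(round(assoc$binary$fisher_p, 2), 0.02)
})

test_that("extreme-indicator statistic and null calibration behave", {
  grp <- rep(c(1L, 2L), c(7, 16))
  # forced maximum: every indicator deranged in cluster 2 only
  ind <- matrix(rep(c(0, 1), c(7, 16)), 23, 7)
  ext <- extreme_indicator_test(ind, grp, n_perm = 1000, seed = 2)
  expect_equal(ext$statistic, 7L)
  expect_equal(ext$max_cluster, 2L)
  # independent indicators: p is not systematically small
  ps <- vapply(1:30, function(s) {
    set.seed(9000 + s)
    ind0 <- matrix(rbinom(23 * 5, 1, 0.4), 23, 5)
    extreme_indicator_test(ind0, grp, n_perm = 1000, seed = s)$p_value
  }, 0)
  expect_gt(mean(ps), 0.3)
  expect_gt(mean(ps > 0.2), 0.5)
  expect_error(extreme_indicator_test(matrix(0, 23, 1), grp), "two indicators")
  expect_error(extreme_indicator_test(matrix(0, 23, 3), grp, n_perm = 10),
               "at least 1000")
})

test_that("candidate selection lists exactly the panel members", {
  coh <- generate_cohort(small_config(seed = 74))
  run <- select_panels(coh$abundance, labels_of(coh), n_iter = 3, seed = 4)
  cand <- select_candidates(run)
  members <- unique(unlist(strsplit(run$iterations$panel, "+", fixed = TRUE)))
  expect_setequal(cand, members)
  expect_lte(length(cand), 3 * 4)
})
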