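# The synthetic-cohort generator: determinism, planted structure, and the
# null behaviour every downstream test relies on.

test_that("a fixed seed gives a bit-identical cohort", {
  a <- generate_cohort(small_config(seed = 5))
  b <- generate_cohort(small_config(seed = 5))
  expect_identical(a$abundance, b$abundance)
  expect_identical(a$metadata, b$metadata)
  expect_identical(a$graph$edges, b$graph$edges)
  expect_identical(a$truth$subtype_labels, b$truth$subtype_labels)
  c <- generate_cohort(small_config(seed = 6))
  expect_false(identical(a$abundance, c$abundance))
})

test_that("study-sized configuration yields a 73 x 226 positive matrix", {
  coh <- generate_cohort(synth_config(n_cases = 23, n_controls = 50,
                                      n_proteins = 226, seed = 2))
  expect_equal(dim(coh$abundance), c(73L, 226L))
  expect_true(all(coh$abundance > 0, na.rm = TRUE))
  expect_equal(sum(coh$metadata$label == "case"), 23L)
  # truth subtype labels are defined for cases only
  expect_setequal(names(coh$truth$subtype_labels),
                  coh$metadata$sample_id[coh$metadata$label == "case"])
})

test_that("invalid configurations are rejected", {
  expect_error(synth_config(n_cases = 0), "positive")
  expect_error(synth_config(block_sizes = rep(30, 10), n_proteins = 100),
               "block_sizes")
  expect_error(synth_config(n_signal = 100, n_subtype_markers = 150,
                            n_proteins = 226), "exceeds")
  expect_error(synth_config(block_rho = 1), "block_rho")
  expect_error(synth_config(missing_rate = 1), "missing_rate")
})

test_that("a null configuration carries no case-control signal", {
  # per-protein two-sample t statistics over 50 seeds average to ~0
  tstats <- c()
  for (s in 1:50) {
    coh <- generate_cohort(small_config(seed = 1000 + s, n_proteins = 30,
                                        n_signal = 0, subtype_effect = 0))
    lg <- log2(coh$abundance)
    y <- coh$metadata$label == "case"
    d <- colMeans(lg[y, ]) - colMeans(lg[!y, ])
    sdp <- apply(lg, 2, sd)
    tstats <- c(tstats, d / (sdp * sqrt(1 / sum(y) + 1 / sum(!y))))
  }
  expect_lt(abs(mean(tstats)), 0.1)
})

test_that("planted log2 effects are recovered at large n", {
  coh <- generate_cohort(synth_config(n_cases = 500, n_controls = 500,
                                      n_proteins = 30, block_sizes = rep(4, 3),
                                      seed = 77))
  lg <- log2(coh$abundance)
  y <- coh$metadata$label == "case"
  for (pr in coh$truth$signal_proteins) {
    d <- mean(lg[y, pr]) - mean(lg[!y, pr])
    se <- sd(lg[, pr]) * sqrt(1 / 500 + 1 / 500)
    expect_lt(abs(d - 1.5), 3 * se)
  }
})

test_that("within-block log-abundance correlations match block_rho", {
  coh <- generate_cohort(synth_config(n_cases = 150, n_controls = 150,
                                      n_proteins = 40, block_sizes = rep(6, 3),
                                      block_rho = 0.7, seed = 4))
  lg <- log2(coh$abundance)
  for (b in coh$truth$blocks) {
    cm <- cor(lg[, b])
    expect_equal(mean(cm[upper.tri(cm)]), 0.7, tolerance = 0.08)
  }
})

test_that("missing values are injected at the configured rate", {
  coh <- generate_cohort(small_config(seed = 9, missing_rate = 0.1))
  rate <- mean(is.na(coh$abundance))
  expect_lt(abs(rate - 0.1), 0.02)
  expect_true(all(rowSums(!is.na(coh$abundance)) > 0))
})

test_that("interaction graph guarantees signal degree and simplicity", {
  prot <- sprintf("P%03d", 1:50)
  g <- generate_interaction_graph(prot, signal_ids = prot[1:4],
                                  min_signal_degree = 4, seed = 3)
  deg <- graph_degree(g, prot)
  expect_true(all(deg[prot[1:4]] >= 4))
  expect_true(all(g$edges[, 1] < g$edges[, 2]))      # no self-loops
  expect_equal(anyDuplicated(paste(g$edges[, 1], g$edges[, 2])), 0L)
  expect_identical(g$edges,
                   generate_interaction_graph(prot, prot[1:4], 4,
                                              seed = 3)$edges)
  # zero background: only signal proteins and their forced partners connect
  g0 <- generate_interaction_graph(prot, signal_ids = prot[1:2],
                                   min_signal_degree = 4,
                                   background_degree_mean = 0, seed = 3)
  deg0 <- graph_degree(g0, prot)
  touched <- unique(as.vector(g0$edges))
  expect_true(all(deg0[setdiff(prot, touched)] == 0))
  expect_true(all(prot[1:2] %in% touched))
  expect_error(generate_interaction_graph(prot, signal_ids = "XXX"),
               "unknown protein")
})

test_that("clinical generator ties severity and indicators to subtype 2", {
  subtype <- rep(c(1L, 2L), c(7, 16))
  names(subtype) <- sprintf("case%02d", 1:23)
  # forced maximum: all indicators at prevalence 1 in subtype 2, 0 in 1
  probs <- list(subtype1 = rep(0, 7), subtype2 = rep(1, 7))
  cl <- generate_clinical(subtype, derangement_probs = probs, seed = 2)
  ind <- cl[, grep("indicator", names(cl))]
  ext <- extreme_indicator_test(ind, subtype, n_perm = 1000, seed = 1)
  expect_equal(ext$statistic, 7L)
  # default prevalences put every indicator higher in subtype 2
  probs_def <- default_derangement_probs()
  expect_true(all(probs_def$subtype2 > probs_def$subtype1))
  expect_error(generate_clinical(subtype,
                                 derangement_probs = list(subtype1 = c(0, 2),
                                                          subtype2 = c(0, 1))),
               "\\[0, 1\\]")
})

test_that("with no severity shift, subtype association is at chance level", {
  subtype <- rep(c(1L, 2L), c(10, 13))
  ps <- vapply(1:40, function(s) {
    cl <- generate_clinical(subtype, severity_shift = 0,
                            derangement_probs = list(subtype1 = rep(0.3, 7),
                                                     subtype2 = rep(0.3, 7)),
                            seed = 3000 + s)
    wilcoxon_rank_sum(cl$protein_24h[subtype == 1],
                      cl$protein_24h[subtype == 2])$p_value
  }, 0)
  # p-values should look uniform: mean near 0.5, spread over the range
  expect_gt(mean(ps), 0.32)
  expect_lt(mean(ps), 0.68)
  expect_gt(mean(ps < 0.5), 0.25)
})
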