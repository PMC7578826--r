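# Quantitative filters: worked arithmetic, accounting identities, and the
# degree-greedy correlation pruning against a brute-force oracle.

mk <- function(values, samples = NULL, proteins = NULL) {
  m <- as.matrix(values)
  rownames(m) <- samples %||% sprintf("s%d", seq_len(nrow(m)))
  colnames(m) <- proteins %||% sprintf("P%d", seq_len(ncol(m)))
  m
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("TIC normalisation divides by per-sample totals and is idempotent", {
  m <- mk(rbind(c(2, 2), c(1, 3)))
  n1 <- tic_normalize(m)
  expect_equal(unname(n1[1, ]), c(0.5, 0.5))
  expect_equal(unname(n1[2, ]), c(0.25, 0.75))
  expect_equal(tic_normalize(n1), n1)
  expect_equal(unname(rowSums(n1)), c(1, 1))
  m2 <- mk(rbind(c(NA, NA), c(1, 1)))
  expect_error(tic_normalize(m2), "no observed values")
})

test_that("reference-median normalisation uses the textbook median", {
  m <- mk(rbind(2, 4, 6, 8), proteins = "A")
  out <- median_reference_normalize(m, c("s1", "s2", "s3"))
  expect_equal(unname(out$abundance["s4", "A"]), 2)       # 8 / median(2,4,6)
  # even-sized reference: mean-of-middle convention, checked against stats::median
  m2 <- mk(rbind(2, 4, 9), proteins = "B")
  out2 <- median_reference_normalize(m2, c("s1", "s2"))
  expect_equal(unname(out2$abundance["s3", "B"]), 9 / median(c(2, 4)))
  # constant protein with all samples as reference becomes exactly 1
  m3 <- mk(rbind(c(3, 5), c(3, 7), c(3, 9)))
  out3 <- median_reference_normalize(m3, rownames(m3))
  expect_true(all(out3$abundance[, "P1"] == 1))
  # all-missing reference values are excluded with a reason
  m4 <- mk(rbind(c(NA, 1), c(NA, 2), c(5, 3)))
  out4 <- median_reference_normalize(m4, c("s1", "s2"))
  expect_equal(out4$report$removed$protein, "P1")
  expect_equal(ncol(out4$abundance), 1L)
  expect_equal(out4$report$proteins_out,
               out4$report$proteins_in - nrow(out4$report$removed))
})

test_that("CV filter applies the within-group sd/mean rule", {
  # protein P1 constant (CV 0), P2 has case values (1, 3): CV = sqrt(2)/2
  m <- mk(cbind(rep(2, 6), c(1, 3, 2, 2, 2, 2)))
  labels <- rep(c("case", "control"), c(2, 4))
  out <- cv_filter(m, labels, max_cv = 0.30)
  expect_equal(colnames(out$abundance), "P1")
  expect_equal(out$report$removed$protein, "P2")
  expect_match(out$report$removed$reason, "cases")
  expect_true(grepl("0.707", out$report$removed$reason))
  # a vacuous ceiling removes nothing
  out2 <- cv_filter(m, labels, max_cv = Inf)
  expect_equal(ncol(out2$abundance), 2L)
  expect_equal(nrow(out2$report$removed), 0L)
})

test_that("correlation pruning keeps the higher-degree protein", {
  # exact sample correlations built from orthogonal contrasts:
  # cor(A,B) = cor(A,C) = 0.8, cor(B,C) = 0.28
  u <- c(1, -1, 1, -1) / 2
  v <- c(1, 1, -1, -1) / 2
  m <- mk(2^cbind(u, 0.8 * u + 0.6 * v, 0.8 * u - 0.6 * v),
          proteins = c("A", "B", "C"))
  cm <- cor(log2(m))
  expect_equal(cm["A", "B"], 0.8, tolerance = 1e-12)
  expect_equal(cm["B", "C"], 0.28, tolerance = 1e-12)
  out <- prune_correlated(m, threshold = 0.7)
  expect_equal(colnames(out$abundance), "A")
  expect_setequal(out$report$removed$protein, c("B", "C"))
  expect_true(all(grepl("retained A", out$report$removed$reason)))

  # brute force: A ({A}) is the unique maximal survivor set in which no
  # retained pair reaches the threshold and removals are degree-justified
  adj <- abs(cm) >= 0.7; diag(adj) <- FALSE
  deg <- rowSums(adj)
  valid <- function(keep) {
    if (any(adj[keep, keep])) return(FALSE)
    all(vapply(setdiff(colnames(m), keep), function(q)
      any(adj[q, keep] & deg[keep] >= deg[q]), logical(1)))
  }
  sets <- unlist(lapply(1:3, function(k)
    combn(colnames(m), k, simplify = FALSE)), recursive = FALSE)
  expect_identical(Filter(valid, sets), list("A"))
})

test_that("pruning is idempotent and handles duplicates and identity cases", {
  set.seed(21)
  m <- matrix(2^rnorm(20 * 12), 20, 12,
              dimnames = list(sprintf("s%d", 1:20), sprintf("P%02d", 1:12)))
  m[, 7] <- m[, 3]            # exact duplicate pair
  out <- prune_correlated(m, threshold = 0.7)
  expect_true(xor("P03" %in% colnames(out$abundance),
                  "P07" %in% colnames(out$abundance)))
  cm <- abs(cor(log2(out$abundance)))
  diag(cm) <- 0
  expect_true(all(cm < 0.7))
  again <- prune_correlated(out$abundance, threshold = 0.7)
  expect_equal(nrow(again$report$removed), 0L)
  expect_identical(again$abundance, out$abundance)
  # nothing at threshold: identity
  id <- prune_correlated(mk(2^diag(6) + 1), threshold = 0.999999)
  expect_equal(ncol(id$abundance), 6L)
})

test_that("network filter retains exactly the proteins with enough edges", {
  prot <- c("A", "B", "C")
  edges <- rbind(c("A", "B"), c("A", "C"), c("A", "D"), c("A", "E"),
                 c("B", "C"), c("B", "D"), c("B", "E"))
  g <- interaction_graph(prot, edges)
  m <- mk(matrix(1:9, 3, 3), proteins = prot)
  out <- network_filter(m, g, min_edges = 4)   # deg A=5? no: A has 4, B 4, C 2
  expect_setequal(colnames(out$abundance), c("A", "B"))
  expect_equal(out$report$removed$protein, "C")
  expect_equal(ncol(network_filter(m, g, min_edges = 0)$abundance), 3L)
  empty <- interaction_graph(prot)
  expect_equal(ncol(network_filter(m, empty, min_edges = 1)$abundance), 0L)
})

test_that("the composed pipeline preserves accounting at every stage", {
  coh <- generate_cohort(small_config(seed = 12, cv_noise = 0.25))
  prep <- preprocess_abundance(coh$abundance, labels_of(coh), coh$graph)
  for (r in prep$reports)
    expect_equal(r$proteins_out, r$proteins_in - nrow(r$removed))
  expect_true(all(colnames(prep$restricted) %in% colnames(prep$full)))
  # restricted proteins all meet the degree threshold
  deg <- graph_degree(coh$graph, colnames(prep$restricted))
  expect_true(all(deg >= 4))
})
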