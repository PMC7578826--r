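# The panel-selection engine: enumeration, inner CV, the selection rule,
# and the iterated driver's invariants.

test_that("panel enumeration counts follow the binomial sums", {
  expect_length(enumerate_panels(letters[1:10], 4), 385)  # 10+45+120+210
  expect_length(enumerate_panels(letters[1:4], 4), 15)    # 2^4 - 1
  expect_true(all(lengths(enumerate_panels(letters[1:6], 1)) == 1))
  expect_identical(enumerate_panels(c("a", "b"), 4),
                   list("a", "b", c("a", "b")))
  expect_error(enumerate_panels(character()), "empty")
})

test_that("the selection rule is lexicographic in AUC, SD, AIC, size", {
  ev <- function(panel, mean_auc, sd_auc, aic = 10)
    list(panel = panel, mean_auc = mean_auc, sd_auc = sd_auc, aic = aic)
  expect_equal(select_best_panel(list(ev("A", 0.8, 0.1), ev("B", 0.9, 0.3))),
               "B")
  expect_equal(select_best_panel(list(ev("A", 0.8, 0.1), ev("B", 0.8, 0.05))),
               "B")
  expect_equal(select_best_panel(list(ev("A", 0.8, 0.1, 12),
                                      ev("B", 0.8, 0.1, 9))), "B")
  expect_equal(select_best_panel(list(ev(c("A", "B"), 0.8, 0.1),
                                      ev("C", 0.8, 0.1))), "C")
  expect_equal(select_best_panel(list(ev("B", 0.8, 0.1), ev("A", 0.8, 0.1))),
               "A")
})

test_that("ensemble ranking puts a strongly separating protein first", {
  first <- 0L
  for (s in 1:100) {
    coh <- generate_cohort(synth_config(n_cases = 29, n_controls = 29,
                                        n_proteins = 60,
                                        block_sizes = rep(5, 4),
                                        n_signal = 1, signal_effect = 2,
                                        n_subtype_markers = 0,
                                        seed = 7000 + s))
    rk <- ensemble_rank(coh$abundance, labels_of(coh))
    if (rk[1] == coh$truth$signal_proteins) first <- first + 1L
  }
  expect_gte(first, 95L)
})

test_that("ensemble ranking is deterministic and order-invariant", {
  coh <- generate_cohort(small_config(seed = 41))
  m <- coh$abundance
  y <- labels_of(coh)
  r1 <- ensemble_rank(m, y)
  perm <- sample(nrow(m))
  expect_identical(ensemble_rank(m[perm, ], y[perm]), r1)
  # identical columns tie and break lexicographically
  dup <- m[, rep(1, 4)]
  colnames(dup) <- c("Pd", "Pa", "Pc", "Pb")
  expect_identical(ensemble_rank(dup, y), c("Pa", "Pb", "Pc", "Pd"))
  # a constant protein ranks last
  m2 <- m
  m2[, "P010"] <- 3
  expect_equal(ensemble_rank(m2, y)[ncol(m2)], "P010")
})

test_that("inner CV reaches the ceiling on perfectly separated data", {
  set.seed(8)
  n <- 40
  y <- rep(c("case", "control"), each = n / 2)
  m <- matrix(2^rnorm(n * 3), n,
              dimnames = list(sprintf("s%d", 1:n), c("A", "B", "C")))
  m[y == "case", "A"] <- m[y == "case", "A"] * 2^12
  res <- cv_evaluate("A", m, y, n_folds = 5, seed = 1)
  expect_equal(res$mean_auc, 1)
  expect_equal(res$sd_auc, 0)
  # determinism: identical folds, identical result
  expect_identical(cv_evaluate(c("A", "B"), m, y, seed = 9),
                   cv_evaluate(c("A", "B"), m, y, seed = 9))
  expect_error(cv_evaluate("Z", m, y), "not in matrix")
})

test_that("inner CV on permuted labels centres at AUC one half", {
  set.seed(14)
  n <- 60
  m <- matrix(2^rnorm(n * 4), n,
              dimnames = list(sprintf("s%d", 1:n), c("A", "B", "C", "D")))
  aucs <- vapply(1:100, function(r) {
    y <- sample(rep(c("case", "control"), each = n / 2))
    cv_evaluate(c("A", "B"), m, y, n_folds = 5, seed = r)$mean_auc
  }, 0)
  expect_equal(mean(aucs), 0.5, tolerance = 0.03)
})

test_that("the iterated driver is deterministic with sound accounting", {
  coh <- generate_cohort(small_config(seed = 51))
  m <- coh$abundance
  y <- labels_of(coh)
  r1 <- select_panels(m, y, n_iter = 4, seed = 99)
  r2 <- select_panels(m, y, n_iter = 4, seed = 99)
  expect_identical(r1$iterations, r2$iterations)
  expect_identical(r1$panel_freq, r2$panel_freq)
  # panel counts sum to the number of iterations
  expect_equal(sum(r1$panel_freq$count), 4L)
  # a protein's count is at least that of any panel containing it
  for (i in seq_len(nrow(r1$panel_freq))) {
    members <- strsplit(r1$panel_freq$panel[i], "+", fixed = TRUE)[[1]]
    for (pr in members)
      expect_gte(r1$protein_freq$count[r1$protein_freq$protein == pr],
                 r1$panel_freq$count[i])
  }
  # panels come from the iteration shortlist and respect the size cap
  for (i in 1:4) {
    members <- strsplit(r1$iterations$panel[i], "+", fixed = TRUE)[[1]]
    expect_lte(length(members), 4L)
    expect_true(all(members %in% r1$shortlists[[i]]))
  }
  # partitions are disjoint, stratified 80/20, and cover all samples
  for (p in r1$partitions) {
    expect_length(intersect(p$train, p$validation), 0L)
    expect_setequal(c(p$train, p$validation), rownames(m))
    expect_equal(sum(y[p$train] == "case"), round(0.8 * sum(y == "case")))
  }
})

test_that("a single iteration yields one panel with count one", {
  coh <- generate_cohort(small_config(seed = 52))
  r <- select_panels(coh$abundance, labels_of(coh), n_iter = 1, seed = 3)
  expect_equal(nrow(r$panel_freq), 1L)
  expect_equal(r$panel_freq$count, 1L)
  expect_equal(r$panel_freq$frequency, 1)
})

test_that("panel CV honours missing values via complete cases", {
  coh <- generate_cohort(small_config(seed = 53, missing_rate = 0.03))
  expect_true(anyNA(coh$abundance))
  r <- select_panels(coh$abundance, labels_of(coh), n_iter = 2, seed = 5)
  expect_true(all(is.finite(r$iterations$outer_auc)))
  expect_true(all(r$iterations$inner_mean_auc >= 0 &
                  r$iterations$inner_mean_auc <= 1))
})
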