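# Case-only subtype discovery and characterisation: candidate restriction,
# silhouette-selected K-means, per-protein differential expression with
# uncapped Bonferroni correction, clinical association tables, and the
# extreme-lab-value permutation test.

#' Candidate proteins for case-only clustering
#'
#' The analytes that occurred in at least one selected panel of an iterated
#' run, ordered by occurrence count (then identifier).
#'
#' @param run A `panel_run` from [select_panels()].
#' @return Character vector of protein identifiers.
#' @export
select_candidates <- function(run) {
  stopifnot(inherits(run, "panel_run"))
  pf <- run$protein_freq
  if (nrow(pf) == 0L)
    stop("no proteins occurred in any selected panel; run more iterations",
         call. = FALSE)
  pf$protein[order(-pf$count, pf$protein)]
}

# Standardised log2 case matrix used by all clustering operations.
cluster_input <- function(case_matrix) {
  validate_abundance(case_matrix)
  z <- scale(log2(case_matrix))
  z[, attr(z, "scaled:scale") == 0] <- 0
  z[is.na(z)] <- 0  # rare missing cells contribute nothing after centring
  z
}

# K-means++ seeding: first centre uniform, later centres with probability
# proportional to the squared distance to the nearest chosen centre.
kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1L] <- sample.int(n, 1L)
  d2 <- rowSums(sweep(x, 2L, x[centers[1L], ])^2)
  for (j in seq_len(k - 1L)) {
    if (all(d2 == 0)) {
      centers[j + 1L] <- sample.int(n, 1L)
    } else {
      centers[j + 1L] <- sample.int(n, 1L, prob = d2)
    }
    d2 <- pmin(d2, rowSums(sweep(x, 2L, x[centers[j + 1L], ])^2))
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of cases
#'
#' Lloyd's algorithm in Euclidean space on standardised log2 abundances,
#' with k-means++ seeding and the best of `n_restarts` restarts by total
#' within-cluster sum of squares. Deterministic given the seed. Cluster
#' labels are renumbered by increasing size, so cluster 1 is the smallest.
#'
#' @param case_matrix Abundance matrix of the cases only.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed.
#' @param n_restarts Number of seeding restarts (default 25).
#' @return List with `assignments` (named integer vector), `sizes`, and
#'   `tot_withinss`.
#' @export
kmeans_cluster <- function(case_matrix, k, seed = 1L, n_restarts = 25L) {
  if (k < 2L) stop("k must be at least 2", call. = FALSE)
  z <- cluster_input(case_matrix)
  if (nrow(z) <= k) stop("need more cases than clusters", call. = FALSE)
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_restarts)) {
      fit <- NULL
      for (try in 1:10) {  # reseed on an empty-cluster outcome
        fit <- tryCatch(
          stats::kmeans(z, centers = kmeanspp_centers(z, k),
                        iter.max = 100L, algorithm = "Lloyd"),
          error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(fit) && all(fit$size > 0L)) break
        fit <- NULL
      }
      if (is.null(fit)) next
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
    }
    if (is.null(best))
      stop("k-means failed to produce a non-degenerate clustering",
           call. = FALSE)
    relabel <- order(order(best$size, seq_len(k)))
    assign <- relabel[best$cluster]
    names(assign) <- rownames(case_matrix)
    list(assignments = assign,
         sizes = as.integer(table(assign)),
         tot_withinss = best$tot.withinss)
  })
}

#' Choose the number of clusters by the average-silhouette method
#'
#' For each k in `k_range`, runs [kmeans_cluster()] and computes the mean
#' silhouette width (Euclidean distances on standardised log2 abundances).
#' The chosen k maximises the mean silhouette; ties go to the smaller k.
#'
#' @param case_matrix Abundance matrix of the cases only.
#' @param k_range Integer range of cluster counts to scan (default 2:6).
#' @param seed Integer seed.
#' @param n_restarts Restarts per k.
#' @return List with `chosen_k` and `silhouette_by_k` (named numeric
#'   vector).
#' @export
choose_k <- function(case_matrix, k_range = 2:6, seed = 1L,
                     n_restarts = 25L) {
  if (min(k_range) < 2L)
    stop("k_range must start at 2 or above", call. = FALSE)
  z <- cluster_input(case_matrix)
  if (nrow(z) <= max(k_range))
    stop("case count must exceed max(k_range)", call. = FALSE)
  d <- stats::dist(z)
  seeds <- spawn_seeds(seed, length(k_range))
  sil <- stats::setNames(numeric(length(k_range)), as.character(k_range))
  for (j in seq_along(k_range)) {
    cl <- kmeans_cluster(case_matrix, k_range[j], seed = seeds[j],
                         n_restarts = n_restarts)
    sw <- cluster::silhouette(cl$assignments, d)
    sil[j] <- mean(sw[, "sil_width"])
  }
  list(chosen_k = k_range[which.max(sil)], silhouette_by_k = sil)
}

#' Case-only subtype discovery
#'
#' The full sub-classification procedure: restrict the case matrix to the
#' candidate proteins, choose k by the average-silhouette method, partition
#' the cases by K-means, and tabulate per-protein differential expression
#' between the clusters (two-sided rank-sum tests with uncapped Bonferroni
#' correction over the candidates).
#'
#' @param case_matrix Abundance matrix of the cases only.
#' @param candidates Protein identifiers to cluster on (e.g. from
#'   [select_candidates()]); defaults to all columns.
#' @param k_range Cluster counts to scan (default 2:6).
#' @param seed Integer seed.
#' @param n_restarts K-means restarts.
#' @return An object of class `subtype_fit`: list with
#'   `candidate_proteins`, `silhouette_by_k`, `chosen_k`, `assignments`,
#'   `cluster_sizes`, `differential` (a `cluster_differential` data frame),
#'   and `pca` (case coordinates on the first three principal components,
#'   display only).
#' @export
cluster_subtypes <- function(case_matrix, candidates = colnames(case_matrix),
                             k_range = 2:6, seed = 1L, n_restarts = 25L) {
  miss <- setdiff(candidates, colnames(case_matrix))
  if (length(miss))
    stop("candidate protein(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  cm <- case_matrix[, candidates, drop = FALSE]
  seeds <- spawn_seeds(seed, 2L)
  ck <- choose_k(cm, k_range = k_range, seed = seeds[1L],
                 n_restarts = n_restarts)
  cl <- kmeans_cluster(cm, ck$chosen_k, seed = seeds[2L],
                       n_restarts = n_restarts)
  z <- cluster_input(cm)
  pca <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  npc <- min(3L, ncol(pca$x))
  out <- list(candidate_proteins = candidates,
              silhouette_by_k = ck$silhouette_by_k,
              chosen_k = ck$chosen_k,
              assignments = cl$assignments,
              cluster_sizes = cl$sizes,
              differential = differential_expression(cm, cl$assignments),
              pca = pca$x[, seq_len(npc), drop = FALSE])
  class(out) <- "subtype_fit"
  out
}

#' @export
print.subtype_fit <- function(x, ...) {
  cat(sprintf("<subtype_fit> %d clusters (sizes %s) over %d candidate proteins\n",
              x$chosen_k, paste(x$cluster_sizes, collapse = "/"),
              length(x$candidate_proteins)))
  cat("  mean silhouette by k: ",
      paste(sprintf("k=%s %.3f", names(x$silhouette_by_k),
                    x$silhouette_by_k), collapse = ", "), "\n")
  sig <- x$differential[x$differential$bonferroni_p < 0.05, , drop = FALSE]
  cat(sprintf("  %d protein(s) differential after Bonferroni correction\n",
              nrow(sig)))
  invisible(x)
}

#' @export
plot.subtype_fit <- function(x, ...) {
  cols <- c("red", "black", "blue", "darkgreen", "orange", "purple")
  graphics::plot(x$pca[, 1L], x$pca[, 2L],
                 col = cols[x$assignments], pch = 19,
                 xlab = "PC1", ylab = "PC2",
                 main = "Case clusters on principal components", ...)
  invisible(x)
}

#' Per-protein differential expression between case clusters
#'
#' Two-sided rank-sum test per protein between the two clusters (for k > 2,
#' the smallest cluster versus the rest), with the higher-expression
#' cluster defined by the larger median and an uncapped Bonferroni
#' correction over the number of proteins tested.
#'
#' @param case_matrix Abundance matrix of the cases (candidate proteins).
#' @param assignments Integer cluster assignments, one per row.
#' @return Data frame of class `cluster_differential`, ordered by raw
#'   p-value, with `protein`, `higher_cluster`, `raw_p`, `bonferroni_p`.
#' @export
differential_expression <- function(case_matrix, assignments) {
  validate_abundance(case_matrix)
  if (length(assignments) != nrow(case_matrix))
    stop("assignments must match rows of case_matrix", call. = FALSE)
  grp <- if (max(assignments) > 2L) as.integer(assignments == 1L) + 1L else
    as.integer(assignments)
  if (length(unique(grp)) < 2L)
    stop("both clusters must be non-empty", call. = FALSE)
  m_tests <- ncol(case_matrix)
  rows <- lapply(colnames(case_matrix), function(pr) {
    a <- case_matrix[grp == 1L, pr]
    b <- case_matrix[grp == 2L, pr]
    w <- wilcoxon_rank_sum(a, b)
    med1 <- stats::median(a, na.rm = TRUE)
    med2 <- stats::median(b, na.rm = TRUE)
    data.frame(protein = pr,
               higher_cluster = if (med1 > med2) 1L else 2L,
               raw_p = w$p_value, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$bonferroni_p <- bonferroni_adjust(out$raw_p, m = m_tests)
  out <- out[order(out$raw_p, out$protein), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "m_tests") <- m_tests
  class(out) <- c("cluster_differential", "data.frame")
  out
}

#' Clinical association of cluster membership
#'
#' Continuous variables: per-cluster medians and a two-sided rank-sum test.
#' Binary variables: a 2x2 table on the evaluable (non-missing) subjects
#' with both the Pearson chi-square (no continuity correction) and the
#' Fisher exact p-value. Bonferroni correction (uncapped) is applied within
#' each table family, `m` = number of variables in the family. Variables
#' with fewer than two evaluable subjects in a cluster are excluded and
#' flagged.
#'
#' @param metadata Data frame of per-case variables (rows aligned with
#'   `assignments`).
#' @param assignments Integer cluster assignments (two clusters).
#' @param continuous,binary Character vectors naming the columns of each
#'   type.
#' @return List with data frames `continuous` (medians per cluster, raw and
#'   Bonferroni p), `binary` (counts and evaluable n per cluster,
#'   chi-square and Fisher raw p, Bonferroni-corrected chi-square p), and
#'   `excluded`.
#' @export
clinical_association <- function(metadata, assignments,
                                 continuous = character(),
                                 binary = character()) {
  if (nrow(metadata) != length(assignments))
    stop("metadata rows must match assignments", call. = FALSE)
  grp <- as.integer(assignments)
  if (!all(grp %in% c(1L, 2L)))
    stop("clinical association expects two clusters", call. = FALSE)
  excluded <- data.frame(variable = character(), reason = character(),
                         stringsAsFactors = FALSE)
  evaluable_ok <- function(v) {
    all(vapply(1:2, function(g) sum(!is.na(v[grp == g])), 0L) >= 2L)
  }

  cont_rows <- list()
  for (v in continuous) {
    val <- metadata[[v]]
    if (!evaluable_ok(val)) {
      excluded <- rbind(excluded, data.frame(
        variable = v, reason = "fewer than 2 evaluable subjects in a cluster",
        stringsAsFactors = FALSE))
      next
    }
    w <- wilcoxon_rank_sum(val[grp == 1L], val[grp == 2L])
    cont_rows[[v]] <- data.frame(
      variable = v,
      median_cluster1 = stats::median(val[grp == 1L], na.rm = TRUE),
      median_cluster2 = stats::median(val[grp == 2L], na.rm = TRUE),
      raw_p = w$p_value, stringsAsFactors = FALSE)
  }
  cont <- if (length(cont_rows)) do.call(rbind, cont_rows) else
    data.frame(variable = character(), median_cluster1 = numeric(),
               median_cluster2 = numeric(), raw_p = numeric())
  if (nrow(cont)) {
    cont$bonferroni_p <- bonferroni_adjust(cont$raw_p, m = nrow(cont))
    rownames(cont) <- NULL
  }

  bin_rows <- list()
  for (v in binary) {
    val <- metadata[[v]]
    if (!evaluable_ok(val)) {
      excluded <- rbind(excluded, data.frame(
        variable = v, reason = "fewer than 2 evaluable subjects in a cluster",
        stringsAsFactors = FALSE))
      next
    }
    tab <- vapply(1:2, function(g) {
      vv <- val[grp == g]
      c(sum(vv == 1L, na.rm = TRUE), sum(vv == 0L, na.rm = TRUE))
    }, numeric(2L))
    t22 <- t(tab)  # rows = cluster, cols = above/below threshold
    chi <- tryCatch(chi_square_2x2(t22)$p_value, error = function(e) NA_real_)
    fis <- fisher_exact_2x2(t22)$p_value
    bin_rows[[v]] <- data.frame(
      variable = v,
      n1_cluster1 = t22[1L, 1L], evaluable_cluster1 = sum(t22[1L, ]),
      n1_cluster2 = t22[2L, 1L], evaluable_cluster2 = sum(t22[2L, ]),
      chisq_p = chi, fisher_p = fis, stringsAsFactors = FALSE)
  }
  bin <- if (length(bin_rows)) do.call(rbind, bin_rows) else
    data.frame(variable = character(), n1_cluster1 = numeric(),
               evaluable_cluster1 = numeric(), n1_cluster2 = numeric(),
               evaluable_cluster2 = numeric(), chisq_p = numeric(),
               fisher_p = numeric())
  if (nrow(bin)) {
    bin$bonferroni_p <- bonferroni_adjust(
      ifelse(is.na(bin$chisq_p), bin$fisher_p, bin$chisq_p), m = nrow(bin))
    rownames(bin) <- NULL
  }
  list(continuous = cont, binary = bin, excluded = excluded)
}

#' Permutation test for concordant extreme laboratory values
#'
#' Tests whether extreme (deranged) laboratory indicators concentrate in a
#' single cluster more than chance allows. The statistic T is the maximum,
#' over clusters, of the number of indicators whose prevalence among the
#' evaluable subjects is strictly greatest in that cluster. The null is
#' generated by permuting the subjects' cluster assignments (cluster sizes
#' and each subject's per-indicator missingness pattern are preserved) and
#' recomputing T; the p-value is `(1 + #permuted T >= observed T) /
#' (1 + n_perm)`.
#'
#' @param indicators Matrix or data frame of 0/1/`NA` indicator values
#'   (rows = cases, columns = indicators; at least two columns).
#' @param assignments Integer cluster assignments, one per row.
#' @param n_perm Number of permutations (default 10000, minimum 1000).
#' @param seed Integer seed.
#' @return List with `p_value`, `statistic` (observed T), `max_cluster`
#'   (the cluster attaining it), `n_perm`, and `n_skipped` (permutations in
#'   which some indicator had a cluster with no evaluable subjects and was
#'   skipped for that permutation).
#' @export
extreme_indicator_test <- function(indicators, assignments, n_perm = 10000L,
                                   seed = 1L) {
  ind <- as.matrix(indicators)
  if (ncol(ind) < 2L)
    stop("need at least two indicators", call. = FALSE)
  if (n_perm < 1000L)
    stop("n_perm must be at least 1000", call. = FALSE)
  if (nrow(ind) != length(assignments))
    stop("assignments must match indicator rows", call. = FALSE)
  grp <- as.integer(assignments)
  gs <- sort(unique(grp))
  stat_T <- function(g) {
    # per cluster x indicator prevalence among evaluable subjects
    prev <- vapply(gs, function(cl) {
      colMeans(ind[g == cl, , drop = FALSE], na.rm = TRUE)
    }, numeric(ncol(ind)))
    prev <- matrix(prev, ncol = length(gs))
    usable <- apply(prev, 1L, function(r) all(is.finite(r)))
    prev <- prev[usable, , drop = FALSE]
    wins <- vapply(seq_along(gs), function(j) {
      sum(apply(prev, 1L, function(r) r[j] > max(r[-j])))
    }, 0L)
    list(T = if (length(wins)) max(wins) else 0L,
         cluster = gs[which.max(wins)],
         skipped = any(!usable))
  }
  obs <- stat_T(grp)
  with_seed(seed, {
    n_skipped <- 0L
    count <- 0L
    for (b in seq_len(n_perm)) {
      st <- stat_T(sample(grp))
      if (st$skipped) n_skipped <- n_skipped + 1L
      if (st$T >= obs$T) count <- count + 1L
    }
    list(p_value = (1 + count) / (1 + n_perm),
         statistic = obs$T,
         max_cluster = obs$cluster,
         n_perm = n_perm,
         n_skipped = n_skipped)
  })
}
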