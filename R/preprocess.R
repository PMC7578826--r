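# Quantitative filters and normalisations applied before any modelling.
# Every filter is a pure function of its inputs and returns the filtered
# matrix together with a `filter_report` whose accounting identity
# (in = out + removed) always holds.

#' Construct a protein interaction graph
#'
#' Undirected simple graph: self-loops are dropped and duplicate edges
#' (in either orientation) collapsed.
#'
#' @param nodes Character vector of protein identifiers.
#' @param edges Two-column character matrix (or data frame) of endpoint
#'   pairs; endpoints need not all be in `nodes` (extras are added).
#' @return An object of class `interaction_graph` with elements `nodes` and
#'   `edges` (canonicalised two-column character matrix).
#' @export
interaction_graph <- function(nodes = character(), edges = NULL) {
  if (is.null(edges)) edges <- matrix(character(0), 0L, 2L)
  edges <- as.matrix(edges)
  if (nrow(edges) > 0L) {
    if (ncol(edges) < 2L) stop("edges need two columns", call. = FALSE)
    edges <- cbind(as.character(edges[, 1L]), as.character(edges[, 2L]))
    loops <- edges[, 1L] == edges[, 2L]
    if (any(loops)) {
      warning(sum(loops), " self-loop(s) dropped")
      edges <- edges[!loops, , drop = FALSE]
    }
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
  }
  nodes <- sort(unique(c(nodes, as.vector(edges))))
  out <- list(nodes = nodes, edges = edges)
  class(out) <- "interaction_graph"
  out
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("<interaction_graph> %d nodes, %d edges\n",
              length(x$nodes), nrow(x$edges)))
  invisible(x)
}

#' Node degrees of an interaction graph
#'
#' @param g An [interaction_graph()].
#' @param proteins Identifiers to report (defaults to the graph's nodes);
#'   proteins absent from the graph have degree 0.
#' @return Named integer vector of degrees.
#' @export
graph_degree <- function(g, proteins = g$nodes) {
  stopifnot(inherits(g, "interaction_graph"))
  tab <- table(factor(as.vector(g$edges), levels = proteins))
  stats::setNames(as.integer(tab), proteins)
}

#' Total-ion-current normalisation
#'
#' Divides each sample's non-missing abundances by that sample's total, so
#' per-sample sums equal 1. Idempotent.
#'
#' @param m Sample-by-protein abundance matrix (`NA` = missing, positive
#'   values).
#' @return The normalised matrix.
#' @export
tic_normalize <- function(m) {
  validate_abundance(m)
  tot <- rowSums(m, na.rm = TRUE)
  if (any(tot == 0))
    stop("sample(s) with no observed values: ",
         paste(rownames(m)[tot == 0], collapse = ", "), call. = FALSE)
  m / tot
}

#' Normalisation to the reference group's median
#'
#' Each protein is divided by its median over the reference samples, so the
#' reference-group median of every retained protein is 1. Proteins whose
#' reference values are all missing cannot be scaled and are removed with a
#' reason in the report.
#'
#' @param m Abundance matrix.
#' @param reference_samples Character vector of reference sample
#'   identifiers (e.g. the controls); must be non-empty and present in `m`.
#' @return List with `abundance` and `report` (a `filter_report`).
#' @export
median_reference_normalize <- function(m, reference_samples) {
  validate_abundance(m)
  if (length(reference_samples) == 0L)
    stop("reference set must be non-empty", call. = FALSE)
  missing_ref <- setdiff(reference_samples, rownames(m))
  if (length(missing_ref))
    stop("unknown reference sample(s): ", paste(missing_ref, collapse = ", "),
         call. = FALSE)
  ref <- m[reference_samples, , drop = FALSE]
  med <- apply(ref, 2L, stats::median, na.rm = TRUE)
  bad <- !is.finite(med) | med <= 0
  removed <- data.frame(protein = colnames(m)[bad],
                        reason = rep("no usable reference values", sum(bad)),
                        stringsAsFactors = FALSE)
  keep <- !bad
  out <- sweep(m[, keep, drop = FALSE], 2L, med[keep], "/")
  list(abundance = out,
       report = filter_report("median_reference_normalize", colnames(m),
                              removed))
}

#' Within-group coefficient-of-variation filter
#'
#' Retains proteins whose CV (`sd/mean` of non-missing values, `n - 1`
#' denominator) is at most `max_cv` in the case group and in the control
#' group separately. Proteins with an undefined CV in either group (fewer
#' than two observed values, or zero mean) fail the filter.
#'
#' @param m Abundance matrix.
#' @param labels Case/control labels, one per row of `m`.
#' @param max_cv CV ceiling (default 0.30).
#' @return List with `abundance` and `report`.
#' @export
cv_filter <- function(m, labels, max_cv = 0.30) {
  validate_abundance(m)
  y <- binarize_labels(labels)
  if (length(y) != nrow(m)) stop("labels must match rows of m", call. = FALSE)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both groups must be non-empty", call. = FALSE)
  group_cv <- function(rows) {
    mm <- m[rows, , drop = FALSE]
    mu <- colMeans(mm, na.rm = TRUE)
    sdv <- apply(mm, 2L, stats::sd, na.rm = TRUE)
    ifelse(is.finite(sdv) & is.finite(mu) & mu != 0, sdv / mu, NA_real_)
  }
  cv1 <- group_cv(y == 1L)
  cv0 <- group_cv(y == 0L)
  fail <- is.na(cv1) | is.na(cv0) | cv1 > max_cv | cv0 > max_cv
  reason <- character(sum(fail))
  bad1 <- is.na(cv1[fail]) | cv1[fail] > max_cv
  reason <- ifelse(is.na(cv1[fail]) | is.na(cv0[fail]),
                   "CV undefined in a group",
                   ifelse(bad1,
                          sprintf("CV %.3f in cases", cv1[fail]),
                          sprintf("CV %.3f in controls", cv0[fail])))
  removed <- data.frame(protein = colnames(m)[fail], reason = reason,
                        stringsAsFactors = FALSE)
  list(abundance = m[, !fail, drop = FALSE],
       report = filter_report("cv_filter", colnames(m), removed))
}

#' Correlation-based redundancy pruning
#'
#' Computes pairwise Pearson correlations of log2 abundances
#' (pairwise-complete observations; undefined correlations are treated
#' as 0). Among proteins linked by `|r| >= threshold`, the protein with the
#' larger number of at-threshold partners (its degree in the correlation
#' graph, computed once on the input and held fixed) displaces its
#' partners; degree ties break lexicographically by protein identifier. No
#' retained pair correlates at or above the threshold, and the operation is
#' idempotent.
#'
#' @param m Abundance matrix.
#' @param threshold Absolute-correlation threshold (default 0.7).
#' @return List with `abundance` and `report`; each removal records the
#'   partner that displaced it.
#' @export
prune_correlated <- function(m, threshold = 0.7) {
  validate_abundance(m)
  p <- ncol(m)
  if (p < 2L)
    return(list(abundance = m,
                report = filter_report("prune_correlated", colnames(m), NULL)))
  lg <- log2(m)
  cm <- suppressWarnings(stats::cor(lg, use = "pairwise.complete.obs"))
  n_undef <- sum(is.na(cm[upper.tri(cm)]))
  cm[is.na(cm)] <- 0
  adj <- abs(cm) >= threshold
  diag(adj) <- FALSE
  deg <- rowSums(adj)
  ord <- order(-deg, colnames(m))
  status <- rep.int(0L, p)  # 0 undecided, 1 kept, -1 removed
  displaced_by <- rep(NA_character_, p)
  for (i in ord) {
    if (status[i] == -1L) next
    status[i] <- 1L
    partners <- which(adj[i, ] & status == 0L)
    if (length(partners)) {
      status[partners] <- -1L
      displaced_by[partners] <- colnames(m)[i]
    }
  }
  rem <- which(status == -1L)
  removed <- data.frame(
    protein = colnames(m)[rem],
    reason = sprintf("|r| >= %.2f with retained %s", threshold,
                     displaced_by[rem]),
    stringsAsFactors = FALSE)
  rep <- filter_report("prune_correlated", colnames(m), removed)
  rep$n_undefined_correlations <- n_undef
  list(abundance = m[, status == 1L, drop = FALSE], report = rep)
}

#' Interaction-network degree filter
#'
#' Retains exactly the proteins with at least `min_edges` documented
#' interactions; proteins absent from the graph have degree 0. The output
#' is the "restricted" dataset of the workflow (the input being the "full"
#' dataset).
#'
#' @param m Abundance matrix.
#' @param g An [interaction_graph()].
#' @param min_edges Minimum degree (default 4).
#' @return List with `abundance` and `report`.
#' @export
network_filter <- function(m, g, min_edges = 4L) {
  validate_abundance(m)
  deg <- graph_degree(g, colnames(m))
  fail <- deg < min_edges
  removed <- data.frame(protein = colnames(m)[fail],
                        reason = sprintf("degree %d < %d", deg[fail],
                                         as.integer(min_edges)),
                        stringsAsFactors = FALSE)
  list(abundance = m[, !fail, drop = FALSE],
       report = filter_report("network_filter", colnames(m), removed))
}

#' Full preprocessing pipeline
#'
#' Composes the quantitative filters in the workflow order: total-ion
#' normalisation, reference-median normalisation (reference = controls),
#' within-group CV filter, correlation pruning, and the interaction-degree
#' filter. The matrix before the degree filter is the "full" dataset; after
#' it, the "restricted" dataset.
#'
#' @param m Abundance matrix.
#' @param labels Case/control labels, one per row.
#' @param graph An [interaction_graph()] (or `NULL` to skip the degree
#'   filter).
#' @param max_cv,cor_threshold,min_edges Filter thresholds.
#' @return List with `full`, `restricted`, and `reports` (one
#'   `filter_report` per stage).
#' @export
preprocess_abundance <- function(m, labels, graph = NULL, max_cv = 0.30,
                                 cor_threshold = 0.7, min_edges = 4L) {
  y <- binarize_labels(labels)
  m1 <- tic_normalize(m)
  ref <- rownames(m)[y == 0L]
  s2 <- median_reference_normalize(m1, ref)
  s3 <- cv_filter(s2$abundance, labels, max_cv = max_cv)
  s4 <- prune_correlated(s3$abundance, threshold = cor_threshold)
  reports <- list(s2$report, s3$report, s4$report)
  full <- s4$abundance
  restricted <- full
  if (!is.null(graph)) {
    s5 <- network_filter(full, graph, min_edges = min_edges)
    restricted <- s5$abundance
    reports <- c(reports, list(s5$report))
  }
  names(reports) <- vapply(reports, `[[`, "", "stage")
  list(full = full, restricted = restricted, reports = reports)
}
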