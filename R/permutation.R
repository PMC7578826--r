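# Permuted-label null for the panel-selection workflow: rerun the full
# engine on label-permuted data and compare the observed and permuted
# outer-AUC distributions.

#' Uniformly permute a label vector
#'
#' Class counts are preserved; the permutation is uniform over all
#' orderings and deterministic given the seed.
#'
#' @param labels Any label vector.
#' @param seed Integer seed.
#' @return The permuted vector (names, if any, stay in place).
#' @export
permute_labels <- function(labels, seed = 1L) {
  out <- with_seed(seed, sample(labels))
  names(out) <- names(labels)
  out
}

#' Observed-versus-permuted workflow comparison
#'
#' Runs [select_panels()] twice on the same matrix: once with the observed
#' case/control labels and once under the permuted-label null (a fresh
#' uniform label permutation at every iteration). Collects the
#' outer-validation AUCs of both runs, their medians, a two-sided rank-sum
#' comparison, and per-protein AUC summaries (mean and SD of the outer AUC
#' over the iterations whose selected panel contains the protein) for the
#' scatter/density diagnostics.
#'
#' @param m Abundance matrix.
#' @param labels Case/control labels.
#' @param n_iter Iterations per condition (default 100).
#' @param seed Integer root seed (spawns one seed per condition).
#' @param ... Further arguments passed to [select_panels()].
#' @return An object of class `perm_comparison`: list with `observed_aucs`,
#'   `permuted_aucs`, `observed_median`, `permuted_median`, `rank_sum_p`,
#'   `protein_summary` (both conditions), and the two `panel_run` objects.
#' @export
compare_permuted <- function(m, labels, n_iter = 100L, seed = 1L, ...) {
  seeds <- spawn_seeds(seed, 2L)
  obs <- select_panels(m, labels, n_iter = n_iter, seed = seeds[1L],
                       permute = FALSE, ...)
  perm <- select_panels(m, labels, n_iter = n_iter, seed = seeds[2L],
                        permute = TRUE, ...)
  oa <- obs$iterations$outer_auc
  pa <- perm$iterations$outer_auc
  out <- list(observed_aucs = oa,
              permuted_aucs = pa,
              observed_median = stats::median(oa),
              permuted_median = stats::median(pa),
              rank_sum_p = wilcoxon_rank_sum(oa, pa)$p_value,
              protein_summary = rbind(
                cbind(condition = "observed", protein_auc_summary(obs)),
                cbind(condition = "permuted", protein_auc_summary(perm))),
              observed_run = obs,
              permuted_run = perm)
  class(out) <- "perm_comparison"
  out
}

#' Per-protein outer-AUC summary of a panel run
#'
#' For every protein that occurs in at least one selected panel: the number
#' of such iterations and the mean and SD of their outer-validation AUCs.
#'
#' @param run A `panel_run` from [select_panels()].
#' @return Data frame with `protein`, `n_iterations`, `mean_auc`, `sd_auc`.
#' @export
protein_auc_summary <- function(run) {
  stopifnot(inherits(run, "panel_run"))
  members <- strsplit(run$iterations$panel, "+", fixed = TRUE)
  long <- data.frame(protein = unlist(members),
                     auc = rep(run$iterations$outer_auc,
                               lengths(members)),
                     stringsAsFactors = FALSE)
  agg <- stats::aggregate(auc ~ protein, data = long, FUN = function(v)
    c(n = length(v), mean = mean(v), sd = if (length(v) > 1L) stats::sd(v) else NA_real_))
  out <- data.frame(protein = agg$protein,
                    n_iterations = as.integer(agg$auc[, "n"]),
                    mean_auc = agg$auc[, "mean"],
                    sd_auc = agg$auc[, "sd"],
                    stringsAsFactors = FALSE)
  out[order(-out$n_iterations, out$protein), , drop = FALSE]
}

#' @export
print.perm_comparison <- function(x, ...) {
  cat("<perm_comparison>\n")
  cat(sprintf("  median outer AUC: observed %.3f vs permuted %.3f (rank-sum p %.2g)\n",
              x$observed_median, x$permuted_median, x$rank_sum_p))
  invisible(x)
}

#' @export
plot.perm_comparison <- function(x, ...) {
  ps <- x$protein_summary
  obs <- ps[ps$condition == "observed", ]
  per <- ps[ps$condition == "permuted", ]
  graphics::plot(per$mean_auc, per$sd_auc, col = "red", pch = 19,
                 xlim = range(ps$mean_auc, na.rm = TRUE),
                 ylim = range(ps$sd_auc, na.rm = TRUE),
                 xlab = "mean outer AUC", ylab = "SD of outer AUC",
                 main = "Per-protein AUC: observed vs permuted", ...)
  graphics::points(obs$mean_auc, obs$sd_auc, col = "blue", pch = 19)
  graphics::legend("topright", legend = c("observed", "permuted"),
                   col = c("blue", "red"), pch = 19, bty = "n")
  invisible(x)
}
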