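# The iterated cross-validated panel-selection engine: outer 80/20
# resampling, ensemble feature ranking, top-10 shortlist, all-subsets
# logistic model search (<= 4 predictors), inner 5-fold CV selection by
# highest mean AUC / lowest SD, outer validation, and frequency
# aggregation.

# ---- internal fast logistic machinery -------------------------------------

# Minimal guarded logistic fit on a design without intercept column.
# Predictors are assumed pre-standardised (the panel engine z-scores the
# outer-training log2 abundances once; logistic MLE predictions are
# invariant to affine predictor transforms, so fold-level refits on the
# shared scale are equivalent).
fast_logit <- function(X, y, ridge = 1e-4, max_iter = 30L) {
  Xi <- cbind(1, X)
  f <- .cpp_logit_irls(Xi, y, 0.0, max_iter, 1e-8)
  sep <- FALSE
  if (f$singular || !f$converged ||
      (ncol(Xi) > 1L && max(abs(f$coefficients[-1L])) > 12) ||
      any(f$fitted < 1e-10) || any(f$fitted > 1 - 1e-10)) {
    sep <- TRUE
    f <- .cpp_logit_irls(Xi, y, ridge, max_iter, 1e-8)
  }
  list(coef = drop(f$coefficients), loglik = f$loglik, separation = sep)
}

# Stratified train indices: per class, round(frac * n_class) samples
# (base-R banker's rounding), drawn uniformly.
stratified_split <- function(y, frac, seed) {
  with_seed(seed, {
    train <- integer(0)
    for (cl in unique(y)) {
      idx <- which(y == cl)
      n_tr <- round(frac * length(idx))
      if (n_tr < 1L || n_tr >= length(idx))
        stop("split fraction leaves an empty training or validation class",
             call. = FALSE)
      train <- c(train, sample(idx, n_tr))
    }
    sort(train)
  })
}

# Stratified fold assignment: within each class, a random permutation dealt
# round-robin into n_folds near-equal groups.
stratified_folds <- function(y, n_folds, seed) {
  if (min(table(y)) < n_folds)
    stop("n_folds exceeds the minority-class count", call. = FALSE)
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- which(y == cl)
      fold[sample(idx)] <- rep_len(seq_len(n_folds), length(idx))
    }
    fold
  })
}

# ---- exported operations ---------------------------------------------------

#' Ensemble feature ranking of proteins in a training set
#'
#' Each protein is scored by three bivariate case-vs-control associations
#' on log2 abundance: (a) the AIC of its one-predictor logistic fit, (b)
#' the rank of its two-sample rank-sum p-value, and (c) the rank of its
#' absolute standardised mean difference. The final order is the ascending
#' mean of the three ranks; ties break lexicographically by protein
#' identifier, and degenerate (constant) proteins rank last. Deterministic
#' given its input.
#'
#' @param train_matrix Abundance matrix of the training samples.
#' @param train_labels Case/control labels for the training samples.
#' @return Character vector of protein identifiers, best first.
#' @export
ensemble_rank <- function(train_matrix, train_labels) {
  validate_abundance(train_matrix)
  y <- binarize_labels(train_labels)
  if (!any(y == 1L) || !any(y == 0L))
    stop("both classes must be present in the training set", call. = FALSE)
  ensemble_rank_core(log2(train_matrix), y)
}

ensemble_rank_core <- function(lg, y) {
  prot <- colnames(lg)
  p <- ncol(lg)
  mu <- colMeans(lg, na.rm = TRUE)
  sdv <- apply(lg, 2L, stats::sd, na.rm = TRUE)
  constant <- !is.finite(sdv) | sdv == 0
  aic <- rep(Inf, p)
  smd <- rep(0, p)
  z <- ranksum_z(lg, y)
  m1 <- colMeans(lg[y == 1L, , drop = FALSE], na.rm = TRUE)
  m0 <- colMeans(lg[y == 0L, , drop = FALSE], na.rm = TRUE)
  smd <- ifelse(constant, 0, abs(m1 - m0) / sdv)
  for (j in which(!constant)) {
    v <- (lg[, j] - mu[j]) / sdv[j]
    ok <- !is.na(v)
    if (length(unique(y[ok])) < 2L) next
    f <- fast_logit(matrix(v[ok]), y[ok])
    aic[j] <- 4 - 2 * f$loglik
  }
  score <- (rank(aic) + rank(-abs(z)) + rank(-smd)) / 3
  score[constant] <- Inf
  prot[order(score, prot)]
}

#' Enumerate candidate panels from a shortlist
#'
#' All non-empty subsets of the shortlist up to `max_size` members, in
#' deterministic order (by size, then combination order within the given
#' shortlist order).
#'
#' @param shortlist Character vector of protein identifiers (non-empty).
#' @param max_size Maximum panel size (default 4).
#' @return List of character vectors.
#' @examples
#' length(enumerate_panels(letters[1:10])) # 385
#' @export
enumerate_panels <- function(shortlist, max_size = 4L) {
  if (length(shortlist) == 0L) stop("shortlist is empty", call. = FALSE)
  sizes <- seq_len(min(max_size, length(shortlist)))
  unlist(lapply(sizes, function(k)
    utils::combn(shortlist, k, simplify = FALSE)), recursive = FALSE)
}

#' Cross-validated evaluation of one candidate panel
#'
#' Stratified partition of the training samples into `n_folds` near-equal
#' disjoint subsets; for each fold, a logistic model on the panel is fitted
#' to the remaining folds and its AUC computed on the held-out fold.
#' Returns the mean and standard deviation of the fold AUCs plus the AIC of
#' the model refitted on the whole training set.
#'
#' @param panel Character vector of protein identifiers.
#' @param train_matrix Abundance matrix of the training samples.
#' @param train_labels Case/control labels.
#' @param n_folds Number of folds (must not exceed the minority-class
#'   count).
#' @param seed Integer seed for the fold assignment.
#' @return List with `mean_auc`, `sd_auc`, and `aic`.
#' @export
cv_evaluate <- function(panel, train_matrix, train_labels, n_folds = 5L,
                        seed = 1L) {
  validate_abundance(train_matrix)
  y <- binarize_labels(train_labels)
  miss <- setdiff(panel, colnames(train_matrix))
  if (length(miss))
    stop("panel protein(s) not in matrix: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lg <- log2(train_matrix[, panel, drop = FALSE])
  keep <- stats::complete.cases(lg)
  lg <- lg[keep, , drop = FALSE]; y <- y[keep]
  z <- scale(lg)
  z[, attr(z, "scaled:scale") == 0] <- 0
  folds <- stratified_folds(y, n_folds, seed)
  res <- cv_evaluate_core(z, y, folds, n_folds)
  list(mean_auc = res$mean_auc, sd_auc = res$sd_auc, aic = res$aic)
}

cv_evaluate_core <- function(X, y, folds, n_folds) {
  aucs <- numeric(n_folds)
  for (f in seq_len(n_folds)) {
    tr <- folds != f
    fit <- fast_logit(X[tr, , drop = FALSE], y[tr])
    sc <- drop(X[!tr, , drop = FALSE] %*% fit$coef[-1L]) + fit$coef[1L]
    aucs[f] <- auc01(sc, y[!tr])
  }
  full <- fast_logit(X, y)
  list(mean_auc = mean(aucs), sd_auc = stats::sd(aucs),
       aic = 2 * (ncol(X) + 1L) - 2 * full$loglik, full_fit = full)
}

#' Select the best panel from a set of evaluations
#'
#' Lexicographic selection: greatest mean AUC, then lowest SD of the AUC,
#' then lowest AIC, then smallest panel, then lexicographic member order.
#'
#' @param evaluations A list whose elements have `panel`, `mean_auc`,
#'   `sd_auc`, and `aic`.
#' @return The winning element's `panel`.
#' @export
select_best_panel <- function(evaluations) {
  if (length(evaluations) == 0L) stop("no evaluations given", call. = FALSE)
  mean_auc <- vapply(evaluations, `[[`, 0, "mean_auc")
  sd_auc <- vapply(evaluations, `[[`, 0, "sd_auc")
  aic <- vapply(evaluations, `[[`, 0, "aic")
  size <- vapply(evaluations, function(e) length(e$panel), 0L)
  key <- vapply(evaluations, function(e)
    paste(sort(e$panel), collapse = " "), "")
  ord <- order(-mean_auc, sd_auc, aic, size, key)
  evaluations[[ord[1L]]]$panel
}

#' Iterated cross-validated panel selection
#'
#' The discovery engine. Each iteration: a stratified 80/20 outer split;
#' ensemble feature ranking on the training portion ([ensemble_rank()]);
#' the top `top_k` proteins shortlisted; every panel of at most
#' `max_panel_size` shortlist members evaluated by stratified `n_folds`
#' inner cross-validation ([cv_evaluate()]); the best panel chosen by
#' greatest mean AUC / lowest SD / lowest AIC ([select_best_panel()]),
#' refitted on the full training portion and scored on the held-out
#' validation samples. Panel and protein occurrences are aggregated over
#' iterations; proteins recurring in at least `recurrent_min` selected
#' panels are flagged as recurrent. The whole procedure is a deterministic
#' function of the data and the seed, and validation samples never
#' influence panel selection.
#'
#' @param m Abundance matrix (samples x proteins).
#' @param labels Case/control labels, one per row of `m`.
#' @param n_iter Number of outer iterations (default 100).
#' @param outer_split Training fraction of the outer split (default 0.8).
#' @param top_k Shortlist size (default 10).
#' @param max_panel_size Maximum panel size (default 4).
#' @param n_folds Inner cross-validation folds (default 5).
#' @param recurrent_min Minimum selected-panel occurrences for the
#'   "recurrent" flag (default 5).
#' @param seed Integer root seed.
#' @param permute If `TRUE`, the case/control labels are freshly and
#'   uniformly permuted at the start of every iteration (the permuted-label
#'   null of the workflow).
#' @return An object of class `panel_run`: list with `iterations` (data
#'   frame: iteration, selected panel, inner mean/SD AUC, outer AUC,
#'   separation flag), `partitions` (per-iteration train/validation sample
#'   ids), `shortlists`, `panel_freq` (panel occurrence counts),
#'   `protein_freq` (per-protein occurrence counts with `recurrent` flag),
#'   and the run parameters.
#' @export
select_panels <- function(m, labels, n_iter = 100L, outer_split = 0.8,
                          top_k = 10L, max_panel_size = 4L, n_folds = 5L,
                          recurrent_min = 5L, seed = 1L, permute = FALSE) {
  validate_abundance(m)
  y0 <- binarize_labels(labels)
  if (length(y0) != nrow(m)) stop("labels must match rows of m", call. = FALSE)
  seeds <- matrix(spawn_seeds(seed, 3L * n_iter), ncol = 3L)
  lg_all <- log2(m)
  samples <- rownames(m)

  iter_rows <- vector("list", n_iter)
  partitions <- vector("list", n_iter)
  shortlists <- vector("list", n_iter)
  panels_sel <- vector("list", n_iter)

  for (i in seq_len(n_iter)) {
    y <- if (permute) permute_labels(y0, seed = seeds[i, 1L]) else y0
    one <- run_panel_iteration(lg_all, y, outer_split, top_k, max_panel_size,
                               n_folds, split_seed = seeds[i, 2L],
                               fold_seed = seeds[i, 3L])
    iter_rows[[i]] <- data.frame(
      iteration = i,
      panel = paste(sort(one$panel), collapse = "+"),
      panel_size = length(one$panel),
      inner_mean_auc = one$inner_mean_auc,
      inner_sd_auc = one$inner_sd_auc,
      outer_auc = one$outer_auc,
      separation = one$separation,
      stringsAsFactors = FALSE)
    partitions[[i]] <- list(train = samples[one$train],
                            validation = samples[-one$train])
    shortlists[[i]] <- one$shortlist
    panels_sel[[i]] <- sort(one$panel)
  }

  iterations <- do.call(rbind, iter_rows)
  keys <- vapply(panels_sel, paste, "", collapse = "+")
  tab <- sort(table(keys), decreasing = TRUE)
  panel_freq <- data.frame(panel = names(tab),
                           count = as.integer(tab),
                           frequency = as.numeric(tab) / n_iter,
                           stringsAsFactors = FALSE)
  prot_tab <- sort(table(unlist(panels_sel)), decreasing = TRUE)
  protein_freq <- data.frame(protein = names(prot_tab),
                             count = as.integer(prot_tab),
                             frequency = as.numeric(prot_tab) / n_iter,
                             recurrent = as.integer(prot_tab) >= recurrent_min,
                             stringsAsFactors = FALSE)
  out <- list(iterations = iterations, partitions = partitions,
              shortlists = shortlists, panel_freq = panel_freq,
              protein_freq = protein_freq,
              params = list(n_iter = n_iter, outer_split = outer_split,
                            top_k = top_k, max_panel_size = max_panel_size,
                            n_folds = n_folds, recurrent_min = recurrent_min,
                            seed = seed, permute = permute))
  class(out) <- "panel_run"
  out
}

# One outer iteration on the log2 matrix. Ranking, shortlisting, model
# search and refitting use training rows only.
run_panel_iteration <- function(lg_all, y, outer_split, top_k,
                                max_panel_size, n_folds, split_seed,
                                fold_seed) {
  train <- stratified_split(y, outer_split, split_seed)
  lg_tr <- lg_all[train, , drop = FALSE]
  y_tr <- y[train]
  shortlist <- utils::head(ensemble_rank_core(lg_tr, y_tr), top_k)

  # z-score shortlisted proteins on training statistics (reused for the
  # validation projection: no validation information enters the fit)
  mu <- colMeans(lg_tr[, shortlist, drop = FALSE], na.rm = TRUE)
  sdv <- apply(lg_tr[, shortlist, drop = FALSE], 2L, stats::sd, na.rm = TRUE)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  z_tr <- sweep(sweep(lg_tr[, shortlist, drop = FALSE], 2L, mu), 2L, sdv, "/")

  has_na <- anyNA(z_tr)
  folds_full <- stratified_folds(y_tr, n_folds, fold_seed)
  panels <- enumerate_panels(shortlist, max_panel_size)
  if (!has_na) {
    idx <- lapply(panels, match, shortlist)
    em <- .cpp_panel_cv(z_tr, as.numeric(y_tr), idx,
                        as.integer(folds_full), as.integer(n_folds))
    evals <- lapply(seq_along(panels), function(k)
      list(panel = panels[[k]], mean_auc = em[k, 1L], sd_auc = em[k, 2L],
           aic = em[k, 3L]))
  } else {
    evals <- lapply(panels, function(pn) {
      X <- z_tr[, pn, drop = FALSE]
      ok <- stats::complete.cases(X)
      res <- cv_evaluate_core(X[ok, , drop = FALSE], y_tr[ok],
                              folds_full[ok], n_folds)
      list(panel = pn, mean_auc = res$mean_auc, sd_auc = res$sd_auc,
           aic = res$aic)
    })
  }
  best <- select_best_panel(evals)
  k_best <- which(vapply(evals, function(e)
    identical(e$panel, best), logical(1L)))[1L]
  # refit the winning panel on the full training portion
  Xb <- z_tr[, best, drop = FALSE]
  ok_tr <- stats::complete.cases(Xb)
  fit <- fast_logit(Xb[ok_tr, , drop = FALSE], y_tr[ok_tr])

  lg_va <- lg_all[-train, best, drop = FALSE]
  z_va <- sweep(sweep(lg_va, 2L, mu[best]), 2L, sdv[best], "/")
  ok_va <- stats::complete.cases(z_va)
  sc <- drop(z_va[ok_va, , drop = FALSE] %*% fit$coef[-1L]) + fit$coef[1L]
  outer_auc <- auc_mann_whitney(sc, y[-train][ok_va])

  list(train = train, shortlist = shortlist, panel = best,
       inner_mean_auc = evals[[k_best]]$mean_auc,
       inner_sd_auc = evals[[k_best]]$sd_auc,
       outer_auc = outer_auc, separation = fit$separation)
}

#' @export
print.panel_run <- function(x, ...) {
  p <- x$params
  cat(sprintf("<panel_run> %d iterations%s, outer split %.0f/%.0f, top %d, panels <= %d, %d-fold inner CV\n",
              p$n_iter, if (p$permute) " (permuted labels)" else "",
              100 * p$outer_split, 100 * (1 - p$outer_split), p$top_k,
              p$max_panel_size, p$n_folds))
  cat(sprintf("  median outer AUC %.3f  modal panel %s (%.0f%% of iterations)\n",
              stats::median(x$iterations$outer_auc), x$panel_freq$panel[1L],
              100 * x$panel_freq$frequency[1L]))
  invisible(x)
}

#' @export
summary.panel_run <- function(object, n = 10L, ...) {
  cat(sprintf("Iterated panel selection (%d iterations%s)\n",
              object$params$n_iter,
              if (object$params$permute) ", permuted labels" else ""))
  cat(sprintf("Outer validation AUC: median %.3f, IQR [%.3f, %.3f]\n",
              stats::median(object$iterations$outer_auc),
              stats::quantile(object$iterations$outer_auc, 0.25),
              stats::quantile(object$iterations$outer_auc, 0.75)))
  cat("\nTop panels:\n")
  print(utils::head(object$panel_freq, n), row.names = FALSE)
  cat("\nTop proteins (recurrent = in >=",
      object$params$recurrent_min, "selected panels):\n")
  print(utils::head(object$protein_freq, n), row.names = FALSE)
  invisible(object)
}

#' @export
plot.panel_run <- function(x, n = 15L, ...) {
  pf <- utils::head(x$protein_freq, n)
  graphics::barplot(rev(pf$frequency * 100), names.arg = rev(pf$protein),
                    horiz = TRUE, las = 1, xlab = "panel membership (%)",
                    main = "Most frequent panel proteins", ...)
  invisible(x)
}
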