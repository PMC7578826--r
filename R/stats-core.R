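# Shared statistical primitives. Pure functions, no file I/O.

#' Logistic regression by iteratively reweighted least squares
#'
#' Fits a binomial GLM with logit link. Predictors are standardised
#' internally for numerical stability and the coefficients mapped back to
#' the original scale. When quasi-separation is detected (non-convergence or
#' divergent standardised slopes), the model is refitted with a small ridge
#' penalty (`1e-4` on the standardised slopes) and flagged; the AIC is
#' always computed from the unpenalised log-likelihood at the returned
#' coefficients.
#'
#' @param x Numeric predictor matrix (no intercept column), or `NULL` for an
#'   intercept-only model. Constant columns are allowed; their slope is 0.
#' @param y Binary response (0/1, logical, or a factor-like vector where the
#'   second sorted level is the event).
#' @param max_iter,tol IRLS iteration cap and convergence tolerance on the
#'   coefficient change.
#' @return An object of class `logistic_fit`: a list with `coefficients`
#'   (named, intercept first), `se` (Wald standard errors), `fitted`
#'   (probabilities in (0,1)), `log_likelihood`, `aic`
#'   (`2 * n_params - 2 * log_likelihood`), `converged`, and
#'   `separation_flag`.
#' @examples
#' set.seed(1)
#' x <- matrix(rnorm(100), 50)
#' y <- rbinom(50, 1, plogis(x[, 1]))
#' fit <- fit_logistic(x, y)
#' coef(fit)
#' @export
fit_logistic <- function(x, y, max_iter = 50L, tol = 1e-8) {
  y <- binarize_or_check_binary(y)
  n <- length(y)
  if (length(unique(y)) < 2L)
    stop("y must contain both classes", call. = FALSE)
  if (is.null(x) || (is.matrix(x) && ncol(x) == 0L)) {
    x <- matrix(numeric(0), nrow = n, ncol = 0L)
  } else {
    if (!is.matrix(x)) x <- as.matrix(x)
    if (nrow(x) != n) stop("nrow(x) must equal length(y)", call. = FALSE)
    if (!all(is.finite(x))) stop("columns of x must be finite", call. = FALSE)
  }
  fit <- logit_core(x, y, max_iter = max_iter, tol = tol)
  nm <- c("(Intercept)", colnames(x) %||% paste0("x", seq_len(ncol(x))))
  names(fit$coefficients) <- nm[seq_along(fit$coefficients)]
  names(fit$se) <- names(fit$coefficients)
  out <- list(coefficients = fit$coefficients,
              se = fit$se,
              fitted = fit$fitted,
              log_likelihood = fit$loglik,
              aic = 2 * length(fit$coefficients) - 2 * fit$loglik,
              converged = fit$converged,
              separation_flag = fit$separation)
  class(out) <- "logistic_fit"
  out
}

#' @export
print.logistic_fit <- function(x, ...) {
  cat("<logistic_fit>\n")
  print(round(rbind(coef = x$coefficients, se = x$se), 4))
  cat(sprintf("logLik %.4f  AIC %.4f  converged %s%s\n",
              x$log_likelihood, x$aic, x$converged,
              if (x$separation_flag) "  [separation: ridge fallback]" else ""))
  invisible(x)
}

#' @export
coef.logistic_fit <- function(object, ...) object$coefficients

# Internal fast path used throughout the panel engine. `x` has no intercept
# column. Standardises internally, detects separation, and applies the ridge
# fallback. Returns original-scale coefficients.
logit_core <- function(x, y, max_iter = 50L, tol = 1e-8, ridge = 1e-4,
                       want_se = TRUE) {
  n <- length(y)
  p <- ncol(x)
  if (p > 0L) {
    mu <- colMeans(x)
    sdv <- apply(x, 2L, stats::sd)
    keep <- is.finite(sdv) & sdv > 0
    xs <- x[, keep, drop = FALSE]
    if (ncol(xs) > 0L)
      xs <- sweep(sweep(xs, 2L, mu[keep]), 2L, sdv[keep], "/")
  } else {
    keep <- logical(0)
    xs <- x
  }
  X <- cbind(1, xs)
  fit <- .cpp_logit_irls(X, as.numeric(y), 0.0, as.integer(max_iter), tol)
  sep <- FALSE
  slopes <- fit$coefficients[-1L]
  if (fit$singular || !fit$converged ||
      (length(slopes) && max(abs(slopes)) > 12) ||
      any(fit$fitted < 1e-10) || any(fit$fitted > 1 - 1e-10)) {
    sep <- TRUE
    fit <- .cpp_logit_irls(X, as.numeric(y), ridge, as.integer(max_iter), tol)
    if (fit$singular)
      stop("singular design in logistic fit even after ridge penalty",
           call. = FALSE)
  }
  bs <- drop(fit$coefficients)
  se_s <- if (want_se) drop(.cpp_logit_se(X, fit$coefficients,
                                          if (sep) ridge else 0.0)) else
    rep(NA_real_, length(bs))
  # map standardised coefficients back to the original predictor scale
  beta <- numeric(p + 1L)
  se <- rep(0, p + 1L)
  beta[1L] <- bs[1L]
  se[1L] <- se_s[1L]
  if (any(keep)) {
    sl <- bs[-1L] / sdv[keep]
    beta[1L] <- bs[1L] - sum(bs[-1L] * mu[keep] / sdv[keep])
    beta[which(keep) + 1L] <- sl
    se[which(keep) + 1L] <- se_s[-1L] / sdv[keep]
    # intercept SE on the original scale is not propagated exactly through
    # the affine map; recompute from the original-scale information matrix
    # only when requested by fit_logistic (cheap for small p)
    if (want_se) {
      Xo <- cbind(1, x)
      se_o <- tryCatch(drop(.cpp_logit_se(Xo, beta, 0.0)),
                       error = function(e) rep(NA_real_, p + 1L))
      if (all(is.finite(se_o))) se <- se_o
    }
  }
  list(coefficients = beta, se = se, fitted = drop(fit$fitted),
       loglik = fit$loglik, converged = fit$converged || sep,
       separation = sep)
}

binarize_or_check_binary <- function(y) {
  if (is.logical(y)) return(as.integer(y))
  if (is.factor(y)) return(as.integer(y == levels(y)[2L]))
  if (is.character(y)) {
    u <- sort(unique(y))
    if (length(u) > 2L) stop("y has more than two classes", call. = FALSE)
    return(as.integer(y == u[2L]))
  }
  y <- as.numeric(y)
  if (!all(y %in% c(0, 1))) stop("numeric y must be 0/1", call. = FALSE)
  as.integer(y)
}

#' Area under the ROC curve via the Mann-Whitney U statistic
#'
#' Computes `AUC = U / (n1 * n0)` with tied scores counted one half: the
#' probability that a randomly chosen case outscores a randomly chosen
#' control.
#'
#' @param scores Numeric classifier scores (higher = more case-like).
#' @param labels Binary labels (1/`TRUE`/`"case"` = case).
#' @return A single number in \[0, 1\].
#' @examples
#' auc_mann_whitney(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
auc_mann_whitney <- function(scores, labels) {
  y <- binarize_labels(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]; y <- y[ok]
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("both classes must be present to compute an AUC", call. = FALSE)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Unchecked AUC for the hot path: y must already be 0/1 with both classes.
auc01 <- function(scores, y) {
  n1 <- sum(y)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * (length(y) - n1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value under the probability-ordering rule: the sum of
#' hypergeometric probabilities (margins fixed) of all tables no more
#' probable than the observed one.
#'
#' @param t A 2x2 matrix of non-negative counts (rows = groups, columns =
#'   indicator above/below threshold).
#' @return A list with `odds_ratio` (the sample cross-product ratio
#'   `ad/bc`, possibly `Inf`) and `p_value`.
#' @examples
#' fisher_exact_2x2(matrix(c(0, 8, 7, 7), 2))$p_value # ~0.0225
#' @export
fisher_exact_2x2 <- function(t) {
  t <- check_2x2(t)
  p <- if (sum(t) == 0L) 1 else stats::fisher.test(t)$p.value
  or <- (t[1, 1] * t[2, 2]) / (t[1, 2] * t[2, 1])
  list(odds_ratio = or, p_value = min(p, 1))
}

#' Pearson chi-square test for a 2x2 table
#'
#' The Pearson statistic `N (ad - bc)^2 / (r1 r2 c1 c2)` on 1 degree of
#' freedom. The continuity (Yates) correction is off by default.
#'
#' @param t A 2x2 matrix of non-negative counts.
#' @param continuity Apply the Yates continuity correction?
#' @return A list with `statistic` and `p_value`.
#' @examples
#' chi_square_2x2(matrix(c(3, 0, 20, 50), 2)) # chisq = 6.80, p ~ 0.009
#' @export
chi_square_2x2 <- function(t, continuity = FALSE) {
  t <- check_2x2(t)
  if (any(rowSums(t) == 0) || any(colSums(t) == 0))
    stop("chi-square test needs positive row and column margins", call. = FALSE)
  res <- suppressWarnings(stats::chisq.test(t, correct = continuity))
  list(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

check_2x2 <- function(t) {
  t <- as.matrix(t)
  if (!all(dim(t) == c(2L, 2L)))
    stop("expected a 2x2 table", call. = FALSE)
  if (any(t < 0) || any(!is.finite(t)))
    stop("table counts must be finite and non-negative", call. = FALSE)
  t
}

#' Wilcoxon rank-sum (Mann-Whitney) test
#'
#' Exact two-sided p-value when the combined sample is small (`<= 25`) and
#' untied; otherwise the tie-corrected normal approximation (no continuity
#' correction).
#'
#' @param a,b Numeric vectors (both non-empty; `NA`s dropped).
#' @return A list with `statistic` (the Mann-Whitney U for sample `a`) and
#'   `p_value`.
#' @examples
#' wilcoxon_rank_sum(1:3, 4:6)$p_value # exact: 0.1
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) == 0L || length(b) == 0L)
    stop("both samples must be non-empty", call. = FALSE)
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 25L && !ties
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = FALSE))
  list(statistic = unname(res$statistic), p_value = min(res$p.value, 1))
}

# Vectorised rank-sum z-scores for every column of `m` (used for fast
# feature ranking): tie-corrected normal approximation, case vs control.
ranksum_z <- function(m, y) {
  n1 <- sum(y == 1L); n0 <- sum(y == 0L); n <- n1 + n0
  apply(m, 2L, function(v) {
    ok <- !is.na(v)
    if (sum(ok & y == 1L) == 0L || sum(ok & y == 0L) == 0L) return(0)
    vv <- v[ok]; yy <- y[ok]
    m1 <- sum(yy == 1L); m0 <- sum(yy == 0L); nn <- m1 + m0
    r <- rank(vv)
    U <- sum(r[yy == 1L]) - m1 * (m1 + 1) / 2
    tie <- table(vv)
    sig2 <- m1 * m0 / 12 * ((nn + 1) - sum(tie^3 - tie) / (nn * (nn - 1)))
    if (sig2 <= 0) return(0)
    (U - m1 * m0 / 2) / sqrt(sig2)
  })
}
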