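# Per-protein bivariate case-vs-control screen with uncapped Bonferroni
# correction.

#' Uncapped Bonferroni correction
#'
#' Multiplies raw p-values by the number of tests. Values are deliberately
#' not capped at 1: the workflow's differential tables report the raw
#' product (values above 1 simply mean "not significant at any level").
#'
#' @param raw_p Numeric vector of raw p-values in (0, 1\].
#' @param m Number of tests (default: `length(raw_p)`).
#' @return `m * raw_p`, elementwise.
#' @examples
#' bonferroni_adjust(0.012, m = 31) # 0.372
#' @export
bonferroni_adjust <- function(raw_p, m = length(raw_p)) {
  if (length(m) != 1L || !is.finite(m) || m < 1)
    stop("m must be a single integer >= 1", call. = FALSE)
  if (any(raw_p <= 0 | raw_p > 1, na.rm = TRUE))
    stop("raw p-values must lie in (0, 1]", call. = FALSE)
  m * raw_p
}

#' Bivariate logistic screen of every protein
#'
#' For each protein, fits a one-predictor logistic regression of the
#' case/control label on the standardised log2 abundance and reports the
#' Wald p-value of the slope, Bonferroni-adjusted (uncapped) over the
#' number of proteins tested. Complete separation is handled by the
#' ridge-guarded fit of [fit_logistic()] and flagged.
#'
#' @param m Abundance matrix (samples x proteins, positive, `NA` allowed;
#'   each protein is screened on its complete cases).
#' @param labels Case/control labels, one per row.
#' @param alpha Family-wise significance level (default 0.05).
#' @param m_tests Number of tests used for the correction; defaults to the
#'   number of proteins in `m`.
#' @return A data frame of class `screen_result`, ranked by adjusted
#'   p-value, with columns `protein`, `direction` (+1 higher in cases),
#'   `raw_p`, `adjusted_p`, `significant` (`adjusted_p < alpha`), and
#'   `separation`.
#' @export
bivariate_screen <- function(m, labels, alpha = 0.05, m_tests = ncol(m)) {
  validate_abundance(m)
  y <- binarize_labels(labels)
  if (length(y) != nrow(m)) stop("labels must match rows of m", call. = FALSE)
  if (sum(y == 1L) < 2L || sum(y == 0L) < 2L)
    stop("each class needs at least two samples", call. = FALSE)
  lg <- log2(m)
  res <- lapply(colnames(m), function(pr) {
    v <- lg[, pr]
    ok <- !is.na(v)
    vv <- v[ok]; yy <- y[ok]
    if (length(unique(yy)) < 2L || stats::sd(vv) == 0) {
      return(data.frame(protein = pr, direction = 0L, raw_p = 1,
                        separation = FALSE, stringsAsFactors = FALSE))
    }
    z <- (vv - mean(vv)) / stats::sd(vv)
    fit <- fit_logistic(matrix(z, dimnames = list(NULL, pr)), yy)
    slope <- fit$coefficients[2L]
    se <- fit$se[2L]
    p <- if (is.finite(se) && se > 0) 2 * stats::pnorm(-abs(slope / se)) else 1
    data.frame(protein = pr, direction = as.integer(sign(slope)),
               raw_p = max(p, .Machine$double.xmin),
               separation = fit$separation_flag, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$adjusted_p <- bonferroni_adjust(out$raw_p, m = m_tests)
  out$significant <- out$adjusted_p < alpha
  out <- out[order(out$adjusted_p, out$protein),
             c("protein", "direction", "raw_p", "adjusted_p", "significant",
               "separation")]
  rownames(out) <- NULL
  attr(out, "m_tests") <- m_tests
  attr(out, "alpha") <- alpha
  class(out) <- c("screen_result", "data.frame")
  out
}

#' @export
print.screen_result <- function(x, n = 10L, ...) {
  cat(sprintf("<screen_result> %d proteins, %d significant at alpha = %g (m = %d)\n",
              nrow(x), sum(x$significant), attr(x, "alpha"),
              attr(x, "m_tests")))
  print.data.frame(utils::head(x, n), digits = 4)
  if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Volcano-style summary of a screen
#'
#' Signed effect direction against `-log10` adjusted p-value, ready for
#' plotting.
#'
#' @param x A `screen_result`.
#' @return Data frame with `protein`, `signed_log10_p` (direction times
#'   `-log10(adjusted_p)`), and `significant`.
#' @export
screen_volcano_table <- function(x) {
  stopifnot(inherits(x, "screen_result"))
  data.frame(protein = x$protein,
             signed_log10_p = x$direction * -log10(pmax(x$adjusted_p,
                                                        .Machine$double.xmin)),
             significant = x$significant,
             stringsAsFactors = FALSE)
}
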