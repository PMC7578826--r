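# Internal helpers shared across modules.

# Deterministically spawn `n` sub-seeds from one root seed without disturbing
# the caller's RNG stream more than once. Values stay below 2^31 - 1.
spawn_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

# Run `expr` under a local RNG state seeded with `seed`.
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Validate a sample-by-protein abundance matrix: numeric matrix, unique
# dimnames, all non-missing entries strictly positive.
validate_abundance <- function(m, allow_nonpositive = FALSE) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("abundance must be a numeric matrix (samples x proteins)", call. = FALSE)
  if (is.null(rownames(m)) || is.null(colnames(m)))
    stop("abundance matrix needs sample row names and protein column names",
         call. = FALSE)
  if (anyDuplicated(rownames(m)))
    stop("duplicate sample identifiers in abundance matrix", call. = FALSE)
  if (anyDuplicated(colnames(m)))
    stop("duplicate protein identifiers in abundance matrix", call. = FALSE)
  if (!allow_nonpositive && any(m <= 0, na.rm = TRUE)) {
    bad <- which(m <= 0, arr.ind = TRUE)[1L, ]
    stop(sprintf("non-positive abundance at sample '%s', protein '%s'",
                 rownames(m)[bad[1L]], colnames(m)[bad[2L]]), call. = FALSE)
  }
  invisible(m)
}

# Coerce a case/control label vector to 0/1 (case = 1), preserving names.
binarize_labels <- function(labels, case = "case") {
  if (is.logical(labels)) return(stats::setNames(as.integer(labels), names(labels)))
  if (is.numeric(labels)) {
    u <- sort(unique(labels))
    if (!all(u %in% c(0, 1)))
      stop("numeric labels must be 0/1", call. = FALSE)
    return(stats::setNames(as.integer(labels), names(labels)))
  }
  labels <- as.character(labels)
  stats::setNames(as.integer(labels == case), names(labels))
}

# A filter-stage report: accounting of proteins in/out plus per-protein
# removal reasons.
filter_report <- function(stage, proteins_in, removed) {
  if (is.null(removed) || nrow(removed) == 0L) {
    removed <- data.frame(protein = character(), reason = character(),
                          stringsAsFactors = FALSE)
  }
  out <- list(stage = stage,
              proteins_in = length(proteins_in),
              proteins_out = length(proteins_in) - nrow(removed),
              removed = removed)
  class(out) <- "filter_report"
  out
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("<filter_report: %s> %d -> %d proteins (%d removed)\n",
              x$stage, x$proteins_in, x$proteins_out, nrow(x$removed)))
  if (nrow(x$removed) > 0L) {
    show <- utils::head(x$removed, 10L)
    cat(paste0("  ", show$protein, ": ", show$reason, collapse = "\n"), "\n")
    if (nrow(x$removed) > 10L)
      cat(sprintf("  ... and %d more\n", nrow(x$removed) - 10L))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
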