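# File readers and writers: abundance CSV (samples in rows), metadata CSV,
# and STRING-export-like edge-list TSV. Empty strings, "NA" and "NaN" are
# accepted as missing tokens.

na_tokens <- c("", "NA", "NaN")

#' Read a sample-by-protein abundance CSV
#'
#' Expects a header row of protein identifiers and a first column of sample
#' identifiers. All non-missing values must be strictly positive; a
#' violation is reported with its sample and protein.
#'
#' @param path Path to the CSV file.
#' @return Numeric matrix (samples x proteins, `NA` = missing).
#' @export
read_abundance <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = na_tokens,
                        stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("abundance file needs sample id + proteins",
                          call. = FALSE)
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate sample identifier(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  if (anyDuplicated(colnames(m)))
    stop("duplicate protein identifier(s) in header", call. = FALSE)
  validate_abundance(m)
  m
}

#' Write an abundance matrix as CSV
#'
#' @param m Abundance matrix.
#' @param path Output path.
#' @export
write_abundance <- function(m, path) {
  df <- data.frame(sample_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a sample metadata CSV
#'
#' Needs `sample_id` and `label` columns; any further columns are carried
#' as clinical variables.
#'
#' @param path Path to the CSV file.
#' @param abundance Optional abundance matrix to cross-validate against:
#'   every metadata sample must be present in the matrix.
#' @return Data frame.
#' @export
read_metadata <- function(path, abundance = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, na.strings = na_tokens,
                        stringsAsFactors = FALSE)
  if (!all(c("sample_id", "label") %in% names(df)))
    stop("metadata needs 'sample_id' and 'label' columns", call. = FALSE)
  if (anyDuplicated(df$sample_id))
    stop("duplicate sample identifier(s) in metadata", call. = FALSE)
  if (!is.null(abundance)) {
    unknown <- setdiff(df$sample_id, rownames(abundance))
    if (length(unknown))
      stop("metadata sample(s) absent from abundance matrix: ",
           paste(unknown, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write sample metadata as CSV
#' @param metadata Data frame with `sample_id` and `label`.
#' @param path Output path.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.csv(metadata, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a protein interaction edge list (TSV)
#'
#' Tolerates the STRING export dialect: an optional header line and an
#' optional third score column (parsed, and filtered at `min_score` if
#' given). Self-loops and duplicate edges are dropped.
#'
#' @param path Path to the TSV file.
#' @param min_score Optional score threshold; edges below it are dropped
#'   (requires a score column).
#' @return An [interaction_graph()].
#' @export
read_edges <- function(path, min_score = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- strsplit(readLines(path, n = 1L), "\t", fixed = TRUE)[[1L]]
  header_words <- c("protein1", "protein2", "node1", "node2", "from", "to",
                    "source", "target", "score", "combined_score")
  has_header <- any(tolower(first) %in% header_words)
  df <- utils::read.delim(path, header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("edge list needs two columns", call. = FALSE)
  edges <- cbind(as.character(df[[1L]]), as.character(df[[2L]]))
  if (!is.null(min_score)) {
    if (ncol(df) < 3L)
      stop("min_score given but edge list has no score column", call. = FALSE)
    edges <- edges[as.numeric(df[[3L]]) >= min_score, , drop = FALSE]
  }
  interaction_graph(edges = edges)
}

#' Write an interaction graph as a two-column TSV edge list
#' @param g An [interaction_graph()].
#' @param path Output path.
#' @param header Write a `protein1/protein2` header line?
#' @export
write_edges <- function(g, path, header = TRUE) {
  df <- data.frame(protein1 = g$edges[, 1L], protein2 = g$edges[, 2L],
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     col.names = header, quote = FALSE)
  invisible(path)
}

#' Write a synthetic cohort to a directory
#'
#' Abundance and metadata as CSV, the interaction graph as TSV, and the
#' ground truth (planted proteins, subtype labels, configuration) as a JSON
#' sidecar.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_abundance(cohort$abundance, file.path(dir, "abundance.csv"))
  write_metadata(cohort$metadata, file.path(dir, "metadata.csv"))
  write_edges(cohort$graph, file.path(dir, "edges.tsv"))
  truth <- cohort$truth
  truth$config <- unclass(truth$config)
  jsonlite::write_json(truth, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
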