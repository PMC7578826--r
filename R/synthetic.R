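# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: lognormal abundances, block-correlated noise (Gaussian copula on
# the log scale), planted case/control signal proteins, two latent case
# subtypes driving subtype-marker proteins and clinical variables, and a
# STRING-like interaction graph.

#' Configuration for a synthetic CMP proteomic cohort
#'
#' Defaults emulate a nested case-control study of early preeclampsia:
#' 23 cases vs 50 controls, 226 proteins, a planted 4-protein discriminative
#' signal, ten correlated 6-protein blocks, and a severe case subtype
#' comprising ~70% of cases marked by 8 subtype-marker proteins.
#'
#' @param n_cases,n_controls,n_proteins Cohort dimensions.
#' @param n_signal Number of planted case-vs-control signal proteins.
#' @param signal_effect Mean log2 abundance shift of signal proteins in
#'   cases.
#' @param block_sizes Integer vector of correlated-block sizes
#'   (`sum(block_sizes) <= n_proteins`); blocks are disjoint from signal and
#'   subtype-marker proteins.
#' @param block_rho Common within-block correlation of log-abundances, in
#'   \[0, 1).
#' @param subtype_fraction Share of cases in the severe subtype (subtype 2),
#'   in (0, 1).
#' @param subtype_effect Log2 shift of subtype-marker proteins in subtype-2
#'   cases.
#' @param n_subtype_markers Number of subtype-marker proteins (disjoint from
#'   the signal proteins).
#' @param missing_rate Probability that any abundance cell is missing
#'   completely at random, in \[0, 1).
#' @param cv_noise Between-sample lognormal sigma (natural-log scale) of
#'   each protein's abundance.
#' @param seed Integer seed; the whole cohort is a deterministic function of
#'   the configuration.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_cases = 23L, n_controls = 50L, n_proteins = 226L,
                         n_signal = 4L, signal_effect = 1.5,
                         block_sizes = rep(6L, 10L), block_rho = 0.7,
                         subtype_fraction = 16 / 23, subtype_effect = 2,
                         n_subtype_markers = 8L, missing_rate = 0,
                         cv_noise = 0.8, seed = 1L) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_proteins = as.integer(n_proteins),
              n_signal = as.integer(n_signal),
              signal_effect = signal_effect,
              block_sizes = as.integer(block_sizes),
              block_rho = block_rho,
              subtype_fraction = subtype_fraction,
              subtype_effect = subtype_effect,
              n_subtype_markers = as.integer(n_subtype_markers),
              missing_rate = missing_rate,
              cv_noise = cv_noise,
              seed = as.integer(seed))
  if (cfg$n_cases < 1L || cfg$n_controls < 1L || cfg$n_proteins < 1L)
    stop("cohort dimensions must be positive", call. = FALSE)
  if (cfg$n_signal < 0L || cfg$n_subtype_markers < 0L)
    stop("protein counts must be non-negative", call. = FALSE)
  if (length(cfg$block_sizes) && any(cfg$block_sizes < 1L))
    stop("block sizes must be positive", call. = FALSE)
  if (sum(cfg$block_sizes) > cfg$n_proteins)
    stop("sum(block_sizes) exceeds n_proteins", call. = FALSE)
  if (cfg$n_signal + cfg$n_subtype_markers > cfg$n_proteins)
    stop("n_signal + n_subtype_markers exceeds n_proteins", call. = FALSE)
  if (cfg$block_rho < 0 || cfg$block_rho >= 1)
    stop("block_rho must be in [0, 1)", call. = FALSE)
  if (cfg$subtype_fraction <= 0 || cfg$subtype_fraction >= 1)
    stop("subtype_fraction must be in (0, 1)", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  if (cfg$cv_noise <= 0)
    stop("cv_noise must be positive", call. = FALSE)
  class(cfg) <- "synth_config"
  cfg
}

#' Generate a synthetic CMP proteomic cohort
#'
#' Abundances follow a per-protein lognormal model: on the log2 scale,
#' `mu_j + effect + (cv_noise / log(2)) * z_ij`, where `z` is standard
#' normal with equicorrelation `block_rho` inside each correlated block
#' (Gaussian copula on the log scale) and independent elsewhere. Planted
#' signal proteins are shifted by `signal_effect` log2 units in cases.
#' Subtype-marker proteins carry a centred subtype contrast: the two case
#' subtypes are separated by `subtype_effect` log2 units while the overall
#' case mean is unchanged, so markers do not act as case-vs-control
#' signal. Missing cells are injected completely at random. The same
#' configuration (including seed) always yields a bit-identical cohort.
#'
#' @param config A [synth_config()].
#' @return A list of class `synthetic_cohort` with elements `abundance`
#'   (samples x proteins matrix, `NA` = missing), `metadata` (data frame
#'   with `sample_id`, `label` and case-only clinical variables), `graph`
#'   (an `interaction_graph`), and `truth` (planted signal proteins, case
#'   subtype labels, subtype-marker proteins, and the configuration).
#' @examples
#' coh <- generate_cohort(synth_config(n_proteins = 40, seed = 7))
#' dim(coh$abundance)
#' @export
generate_cohort <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  seeds <- spawn_seeds(config$seed, 4L)
  n <- config$n_cases + config$n_controls
  p <- config$n_proteins
  sample_ids <- c(sprintf("case%02d", seq_len(config$n_cases)),
                  sprintf("ctrl%02d", seq_len(config$n_controls)))
  protein_ids <- sprintf("P%03d", seq_len(p))
  is_case <- c(rep(TRUE, config$n_cases), rep(FALSE, config$n_controls))

  # role assignment: signal first, then subtype markers, then blocks
  signal <- protein_ids[seq_len(config$n_signal)]
  markers <- protein_ids[config$n_signal + seq_len(config$n_subtype_markers)]
  free <- setdiff(protein_ids, c(signal, markers))
  blocks <- list()
  off <- 0L
  for (b in seq_along(config$block_sizes)) {
    blocks[[b]] <- free[off + seq_len(config$block_sizes[b])]
    off <- off + config$block_sizes[b]
  }

  abundance <- with_seed(seeds[1L], {
    mu <- stats::rnorm(p, mean = 5, sd = 1.5)           # baseline log2 level
    sigma2 <- config$cv_noise / log(2)                  # log2-scale sd
    z <- matrix(stats::rnorm(n * p), n, p)
    if (config$block_rho > 0) {
      for (b in blocks) {
        idx <- match(b, protein_ids)
        shared <- stats::rnorm(n)
        z[, idx] <- sqrt(config$block_rho) * shared +
          sqrt(1 - config$block_rho) * z[, idx]
      }
    }
    lg <- sweep(z * sigma2, 2L, mu, "+")
    if (length(signal))
      lg[is_case, match(signal, protein_ids)] <-
        lg[is_case, match(signal, protein_ids)] + config$signal_effect
    lg
  })

  n_sub2 <- round(config$subtype_fraction * config$n_cases)
  subtype <- with_seed(seeds[2L], {
    s <- rep(1L, config$n_cases)
    s[sample.int(config$n_cases, n_sub2)] <- 2L
    s
  })
  names(subtype) <- sample_ids[is_case]
  if (length(markers)) {
    # centred subtype contrast: the two subtypes are separated by
    # subtype_effect log2 units but the overall case mean is unchanged, so
    # subtype markers do not masquerade as case-vs-control signal
    frac2 <- n_sub2 / config$n_cases
    shift <- ifelse(subtype == 2L,
                    config$subtype_effect * (1 - frac2),
                    -config$subtype_effect * frac2)
    mk <- match(markers, protein_ids)
    abundance[which(is_case), mk] <- abundance[which(is_case), mk] + shift
  }
  abundance <- 2^abundance
  dimnames(abundance) <- list(sample_ids, protein_ids)
  if (config$missing_rate > 0) {
    abundance <- with_seed(seeds[1L] + 1L, {
      drop_mask <- matrix(stats::runif(n * p) < config$missing_rate, n, p)
      # keep at least one observed value per sample and per protein
      for (i in which(rowSums(!drop_mask) == 0L)) drop_mask[i, 1L] <- FALSE
      for (j in which(colSums(!drop_mask) == 0L)) drop_mask[1L, j] <- FALSE
      abundance[drop_mask] <- NA_real_
      abundance
    })
  }

  clinical <- generate_clinical(subtype, seed = seeds[3L])
  metadata <- data.frame(sample_id = sample_ids,
                         label = ifelse(is_case, "case", "control"),
                         stringsAsFactors = FALSE)
  for (v in names(clinical)) {
    col <- rep(NA_real_, n)
    col[is_case] <- clinical[[v]]
    metadata[[v]] <- col
  }

  graph <- generate_interaction_graph(protein_ids, signal_ids = signal,
                                      seed = seeds[4L])

  out <- list(abundance = abundance, metadata = metadata, graph = graph,
              truth = list(signal_proteins = signal,
                           subtype_labels = subtype,
                           subtype_markers = markers,
                           blocks = blocks,
                           config = config))
  class(out) <- "synthetic_cohort"
  out
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cfg <- x$truth$config
  cat(sprintf(paste0("<synthetic_cohort> %d cases / %d controls x %d proteins\n",
                     "  planted signal: %s\n  subtype markers: %s\n",
                     "  graph: %d nodes, %d edges\n"),
              cfg$n_cases, cfg$n_controls, cfg$n_proteins,
              paste(x$truth$signal_proteins, collapse = ", "),
              paste(x$truth$subtype_markers, collapse = ", "),
              length(x$graph$nodes), nrow(x$graph$edges)))
  invisible(x)
}

#' Generate a STRING-like protein interaction graph
#'
#' Erdos-Renyi background edges with expected degree
#' `background_degree_mean`, plus forced edges so that every planted signal
#' protein reaches degree `min_signal_degree` (so the signal always survives
#' a degree filter at that threshold). Undirected, no self-loops, no
#' duplicate edges.
#'
#' @param proteins Character vector of protein identifiers (or a single
#'   integer, interpreted as `P001...Pnnn`).
#' @param signal_ids Identifiers whose degree is forced to at least
#'   `min_signal_degree`; must all be in `proteins`.
#' @param min_signal_degree Minimum degree guaranteed for `signal_ids`.
#' @param background_degree_mean Expected background degree per node.
#' @param seed Integer seed.
#' @return An object of class `interaction_graph`: list with `nodes` and a
#'   two-column character `edges` matrix.
#' @export
generate_interaction_graph <- function(proteins, signal_ids = character(),
                                       min_signal_degree = 4L,
                                       background_degree_mean = 4,
                                       seed = 1L) {
  if (length(proteins) == 1L && is.numeric(proteins))
    proteins <- sprintf("P%03d", seq_len(proteins))
  if (min_signal_degree < 0L)
    stop("min_signal_degree must be non-negative", call. = FALSE)
  bad <- setdiff(signal_ids, proteins)
  if (length(bad))
    stop("unknown protein identifier(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  n <- length(proteins)
  with_seed(seed, {
    p_edge <- if (n > 1L) min(1, background_degree_mean / (n - 1L)) else 0
    edges <- NULL
    if (p_edge > 0) {
      idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
      keep <- stats::runif(nrow(idx)) < p_edge
      edges <- idx[keep, , drop = FALSE]
    } else {
      edges <- matrix(integer(0), 0L, 2L)
    }
    deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
    for (s in match(signal_ids, proteins)) {
      need <- min_signal_degree - deg[s]
      if (need > 0L) {
        linked <- c(edges[edges[, 2L] == s, 1L], edges[edges[, 1L] == s, 2L])
        pool <- setdiff(seq_len(n), c(s, linked))
        add <- sample(pool, min(need, length(pool)))
        edges <- rbind(edges, cbind(pmin(s, add), pmax(s, add)))
        deg <- tabulate(c(edges[, 1L], edges[, 2L]), nbins = n)
      }
    }
    em <- cbind(proteins[edges[, 1L]], proteins[edges[, 2L]])
    interaction_graph(proteins, em)
  })
}

#' Generate case-only clinical variables tied to a latent subtype
#'
#' Continuous severity variables (gestational week at delivery, maximum
#' systolic and diastolic pressure, 24-h urinary protein) are normal around
#' subtype-specific centres: subtype 2 is shifted by `severity_shift`
#' standard deviations in the severe direction of each variable. Binary
#' laboratory derangement indicators are Bernoulli draws with
#' subtype-specific prevalences; the defaults make all 7 indicators more
#' prevalent in subtype 2.
#'
#' @param subtype_labels Integer vector of 1/2 subtype labels (one per
#'   case).
#' @param severity_shift Shift of subtype-2 continuous variables, in SD
#'   units.
#' @param derangement_probs List with numeric vectors `subtype1` and
#'   `subtype2` of per-indicator prevalences in \[0, 1\] (equal lengths).
#' @param indicator_missing_rate Probability that an indicator value is
#'   missing, per cell.
#' @param seed Integer seed.
#' @return A data frame with one row per case: four continuous severity
#'   variables and one 0/1 column per indicator.
#' @export
generate_clinical <- function(subtype_labels, severity_shift = 1,
                              derangement_probs = default_derangement_probs(),
                              indicator_missing_rate = 0, seed = 1L) {
  stopifnot(all(subtype_labels %in% c(1L, 2L)))
  p1 <- derangement_probs$subtype1
  p2 <- derangement_probs$subtype2
  if (length(p1) != length(p2))
    stop("derangement_probs vectors must have equal length", call. = FALSE)
  if (any(c(p1, p2) < 0 | c(p1, p2) > 1))
    stop("derangement probabilities must lie in [0, 1]", call. = FALSE)
  if (indicator_missing_rate < 0 || indicator_missing_rate >= 1)
    stop("indicator_missing_rate must be in [0, 1)", call. = FALSE)
  n <- length(subtype_labels)
  sev <- as.integer(subtype_labels == 2L)
  # centre, sd, and severe direction (+1 higher is worse, -1 lower is worse)
  cont_spec <- list(delivery_week = c(35.2, 1.2, -1),
                    max_systolic = c(158, 12, +1),
                    max_diastolic = c(85, 9, +1),
                    protein_24h = c(400, 220, +1))
  with_seed(seed, {
    out <- list()
    for (v in names(cont_spec)) {
      s <- cont_spec[[v]]
      val <- stats::rnorm(n, mean = s[1] + sev * severity_shift * s[2] * s[3],
                          sd = s[2])
      if (v == "protein_24h") val <- pmax(val, 20)
      out[[v]] <- val
    }
    out <- as.data.frame(out, stringsAsFactors = FALSE)
    nm <- names(p1) %||% sprintf("indicator%d", seq_along(p1))
    for (k in seq_along(p1)) {
      pr <- ifelse(sev == 1L, p2[k], p1[k])
      val <- stats::rbinom(n, 1L, pr)
      if (indicator_missing_rate > 0)
        val[stats::runif(n) < indicator_missing_rate] <- NA_integer_
      out[[nm[k]]] <- val
    }
    rownames(out) <- names(subtype_labels)
    out
  })
}

#' Default per-subtype laboratory derangement prevalences
#'
#' Seven binary indicators (creatinine, fibrinogen, sodium, uric acid, ALT,
#' AST, platelets beyond their clinical thresholds), each strictly more
#' prevalent in the severe subtype.
#'
#' @return List with vectors `subtype1` and `subtype2`.
#' @export
default_derangement_probs <- function() {
  nm <- c("creatinine_high", "fibrinogen_high", "sodium_low",
          "uric_acid_high", "alt_high", "ast_high", "platelets_low")
  list(subtype1 = stats::setNames(c(0.02, 0.02, 0.02, 0.43, 0.14, 0.14, 0.14), nm),
       subtype2 = stats::setNames(c(0.53, 0.66, 0.75, 0.50, 0.20, 0.20, 0.25), nm))
}
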