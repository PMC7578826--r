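# Workflow driver binding the stages together: simulate (or read) a
# cohort, preprocess, screen, select panels, run the permuted-label null,
# cluster the cases, and write CSV/JSON artifacts plus a run manifest.

#' Workflow configuration
#'
#' Collects every threshold of the pipeline with its default: correlation
#' pruning at 0.7, interaction-degree filter at 4 edges, within-group CV
#' ceiling 0.30, screening alpha 0.05, panels of at most 4 of the top 10
#' proteins, 100 outer iterations at an 80/20 split with 5-fold inner CV,
#' cluster scan k = 2..6, and 10000 permutations for the extreme-indicator
#' test. A single root seed deterministically spawns per-stage seeds.
#'
#' @param synth A [synth_config()] used when no input paths are given.
#' @param abundance_path,metadata_path,edges_path Optional input files; all
#'   three must be given together.
#' @param cor_threshold,min_edges,max_cv,alpha,max_panel_size,top_k,n_iter,outer_split,n_folds,k_range,n_perm
#'   Stage parameters (see the stage functions).
#' @param seed Root seed.
#' @return List of class `workflow_config`.
#' @export
workflow_config <- function(synth = synth_config(),
                            abundance_path = NULL, metadata_path = NULL,
                            edges_path = NULL,
                            cor_threshold = 0.7, min_edges = 4L,
                            max_cv = 0.30, alpha = 0.05,
                            max_panel_size = 4L, top_k = 10L,
                            n_iter = 100L, outer_split = 0.8, n_folds = 5L,
                            k_range = 2:6, n_perm = 10000L, seed = 1L) {
  paths <- c(abundance_path, metadata_path, edges_path)
  if (length(paths) > 0L && length(paths) != 3L)
    stop("give abundance_path, metadata_path and edges_path together",
         call. = FALSE)
  stopifnot(cor_threshold > 0, min_edges >= 0, max_cv > 0,
            alpha > 0, alpha < 1, max_panel_size >= 1, top_k >= 1,
            n_iter >= 1, outer_split > 0, outer_split < 1, n_folds >= 2)
  cfg <- list(synth = synth, abundance_path = abundance_path,
              metadata_path = metadata_path, edges_path = edges_path,
              cor_threshold = cor_threshold, min_edges = as.integer(min_edges),
              max_cv = max_cv, alpha = alpha,
              max_panel_size = as.integer(max_panel_size),
              top_k = as.integer(top_k), n_iter = as.integer(n_iter),
              outer_split = outer_split, n_folds = as.integer(n_folds),
              k_range = as.integer(k_range), n_perm = as.integer(n_perm),
              seed = as.integer(seed))
  class(cfg) <- "workflow_config"
  cfg
}

#' Run the whole workflow and write its artifacts
#'
#' Stages (any subset, in this fixed order): `"simulate"` (or read the
#' configured input files), `"preprocess"`, `"screen"`, `"select-panel"`,
#' `"permute"`, `"cluster"`. Each stage writes its CSV/JSON artifacts into
#' `out_dir`; a `manifest.json` records the configuration, package
#' version, per-stage seeds and filter reports. With the same
#' configuration and seed the CSV artifacts are byte-identical across
#' runs.
#'
#' @param config A [workflow_config()].
#' @param out_dir Output directory (created if needed).
#' @param stages Character vector of stages to run.
#' @return Invisibly, a list with the in-memory results of each stage.
#' @export
run_workflow <- function(config = workflow_config(), out_dir,
                         stages = c("simulate", "preprocess", "screen",
                                    "select-panel", "permute", "cluster")) {
  stopifnot(inherits(config, "workflow_config"))
  allowed <- c("simulate", "preprocess", "screen", "select-panel", "permute",
               "cluster")
  bad <- setdiff(stages, allowed)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seeds <- spawn_seeds(config$seed, 6L)
  names(seeds) <- allowed
  res <- list()
  manifest <- list(package = "cmpanel",
                   version = as.character(utils::packageVersion("cmpanel")),
                   timestamp = format(Sys.time(), tz = "UTC"),
                   seed = config$seed,
                   stage_seeds = as.list(seeds),
                   config = config_snapshot(config),
                   reports = list())

  # inputs: simulate or read
  if (!is.null(config$abundance_path)) {
    abundance <- read_abundance(config$abundance_path)
    metadata <- read_metadata(config$metadata_path, abundance)
    graph <- read_edges(config$edges_path)
    extra <- setdiff(unique(as.vector(graph$edges)), colnames(abundance))
    if (length(extra))
      warning(length(extra),
              " edge protein(s) absent from the abundance matrix (ignored)")
  } else {
    cfg_s <- config$synth
    cfg_s$seed <- seeds[["simulate"]]
    cohort <- generate_cohort(cfg_s)
    abundance <- cohort$abundance
    metadata <- cohort$metadata
    graph <- cohort$graph
    if ("simulate" %in% stages) {
      write_cohort(cohort, out_dir)
      res$cohort <- cohort
    }
  }
  labels <- stats::setNames(metadata$label, metadata$sample_id)
  labels <- labels[rownames(abundance)]

  working <- abundance
  if ("preprocess" %in% stages) {
    prep <- preprocess_abundance(abundance, labels, graph,
                                 max_cv = config$max_cv,
                                 cor_threshold = config$cor_threshold,
                                 min_edges = config$min_edges)
    working <- prep$restricted
    if (ncol(working) == 0L)
      stop("preprocessing removed every protein; relax the thresholds",
           call. = FALSE)
    res$preprocess <- prep
    manifest$reports <- lapply(prep$reports, function(r)
      list(stage = r$stage, proteins_in = r$proteins_in,
           proteins_out = r$proteins_out, removed = r$removed))
    write_abundance(working, file.path(out_dir, "abundance_restricted.csv"))
  }

  if ("screen" %in% stages) {
    scr <- bivariate_screen(working, labels, alpha = config$alpha)
    res$screen <- scr
    utils::write.csv(as.data.frame(scr), file.path(out_dir, "screen.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("select-panel" %in% stages) {
    run <- select_panels(working, labels, n_iter = config$n_iter,
                         outer_split = config$outer_split,
                         top_k = config$top_k,
                         max_panel_size = config$max_panel_size,
                         n_folds = config$n_folds,
                         seed = seeds[["select-panel"]])
    res$panel_run <- run
    utils::write.csv(run$iterations, file.path(out_dir, "iterations.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(run$panel_freq, file.path(out_dir, "panel_freq.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(run$protein_freq, file.path(out_dir, "protein_freq.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("permute" %in% stages) {
    if (is.null(res$panel_run))
      stop("the 'permute' stage needs 'select-panel' in the same run",
           call. = FALSE)
    perm <- select_panels(working, labels, n_iter = config$n_iter,
                          outer_split = config$outer_split,
                          top_k = config$top_k,
                          max_panel_size = config$max_panel_size,
                          n_folds = config$n_folds,
                          seed = seeds[["permute"]], permute = TRUE)
    res$permuted_run <- perm
    cmp <- data.frame(
      condition = c("observed", "permuted"),
      median_outer_auc = c(stats::median(res$panel_run$iterations$outer_auc),
                           stats::median(perm$iterations$outer_auc)),
      stringsAsFactors = FALSE)
    utils::write.csv(cmp, file.path(out_dir, "permutation_summary.csv"),
                     row.names = FALSE, quote = FALSE)
    ps <- rbind(cbind(condition = "observed",
                      protein_auc_summary(res$panel_run)),
                cbind(condition = "permuted", protein_auc_summary(perm)))
    utils::write.csv(ps, file.path(out_dir, "protein_auc_summary.csv"),
                     row.names = FALSE, quote = FALSE)
  }

  if ("cluster" %in% stages) {
    if (is.null(res$panel_run))
      stop("the 'cluster' stage needs 'select-panel' in the same run",
           call. = FALSE)
    candidates <- select_candidates(res$panel_run)
    cases <- rownames(abundance)[binarize_labels(labels) == 1L]
    fit <- cluster_subtypes(working[cases, , drop = FALSE],
                            candidates = candidates,
                            k_range = config$k_range,
                            seed = seeds[["cluster"]])
    res$subtypes <- fit
    utils::write.csv(data.frame(sample_id = names(fit$assignments),
                                cluster = fit$assignments,
                                stringsAsFactors = FALSE),
                     file.path(out_dir, "cluster_assignments.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(as.data.frame(fit$differential),
                     file.path(out_dir, "cluster_differential.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(data.frame(sample_id = names(fit$assignments),
                                fit$pca, check.names = FALSE),
                     file.path(out_dir, "cluster_pca.csv"),
                     row.names = FALSE, quote = FALSE)
    meta_cases <- metadata[match(cases, metadata$sample_id), , drop = FALSE]
    ind_cols <- names(default_derangement_probs()$subtype1)
    ind_cols <- intersect(ind_cols, names(meta_cases))
    cont_cols <- intersect(c("delivery_week", "max_systolic",
                             "max_diastolic", "protein_24h"),
                           names(meta_cases))
    if (fit$chosen_k == 2L && (length(cont_cols) || length(ind_cols))) {
      assoc <- clinical_association(meta_cases, fit$assignments,
                                    continuous = cont_cols,
                                    binary = ind_cols)
      res$clinical <- assoc
      if (nrow(assoc$continuous))
        utils::write.csv(assoc$continuous,
                         file.path(out_dir, "clinical_continuous.csv"),
                         row.names = FALSE, quote = FALSE)
      if (nrow(assoc$binary))
        utils::write.csv(assoc$binary,
                         file.path(out_dir, "clinical_binary.csv"),
                         row.names = FALSE, quote = FALSE)
      if (length(ind_cols) >= 2L) {
        ext <- extreme_indicator_test(
          meta_cases[, ind_cols, drop = FALSE], fit$assignments,
          n_perm = config$n_perm, seed = seeds[["cluster"]] )
        res$extreme_test <- ext
        manifest$extreme_indicator_test <- ext[c("p_value", "statistic",
                                                 "n_perm")]
      }
    }
  }

  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(res)
}

config_snapshot <- function(config) {
  snap <- unclass(config)
  snap$synth <- unclass(snap$synth)
  snap
}
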