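# Small cohort configurations used across the unit tests (the full-size
# study dimensions are exercised in the acceptance tests).

small_config <- function(seed = 1L, n_proteins = 40L,
                         block_sizes = if (n_proteins >= 24L)
                           rep(4L, 4L) else integer(),
                         n_subtype_markers = min(4L, n_proteins %/% 3L),
                         ...) {
  synth_config(n_proteins = n_proteins, block_sizes = block_sizes,
               n_subtype_markers = n_subtype_markers, seed = seed, ...)
}

labels_of <- function(cohort) {
  stats::setNames(cohort$metadata$label, cohort$metadata$sample_id)
}

indicator_names <- function() names(default_derangement_probs()$subtype1)

case_indicators <- function(cohort) {
  md <- cohort$metadata
  md[md$label == "case", indicator_names()]
}
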