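#' Simulate one pooled mapping experiment end to end
#'
#' Runs the whole workflow the toolkit models: cross CB4856 males to the
#' mutant strain, self the F1, collect F2 animals until `n_pool`
#' phenotype-selected homozygous mutants are in hand, pool their lysates,
#' PCR the marker panel against the pool, and call the mutation-containing
#' interval from the band pattern.
#'
#' @param mutation_chrom,mutation_pos_bp Location of the causal mutation.
#' @param markers Marker tibble (`marker_id`, `chrom`, `pos_bp`, and
#'   `p_full`/`p_dilute` unless a perfect-detection run is wanted).
#' @param n_pool Number of selected F2 mutants pooled (default 10; small
#'   pools avoid diluting each worm's template).
#' @param penetrance Phenotype penetrance of the homozygous mutant.
#' @param perfect_detection If TRUE, band presence deterministically equals
#'   allele presence in the pool (success-rate anchors forced to 1).
#' @param map Genetic map anchors.
#' @param build Genome build tibble.
#' @param seed Integer seed for the whole experiment.
#' @param batch_size F2 individuals simulated per collection round.
#' @return List with `pool` (segment tibble of the selected mutants),
#'   `observations` (band tibble) and `result` (a `mapping_result`).
#' @export
simulate_mapping_experiment <- function(mutation_chrom, mutation_pos_bp,
                                        markers, n_pool = 10, penetrance = 1,
                                        perfect_detection = FALSE,
                                        map = ce_genetic_map(),
                                        build = ce_genome(), seed = NULL,
                                        batch_size = 60L) {
  if (!is.null(seed)) withr::local_seed(seed)
  markers <- tibble::as_tibble(markers)
  if (perfect_detection) {
    markers$p_full <- 1
    markers$p_dilute <- 1
  }
  stopifnot(all(c("p_full", "p_dilute") %in% names(markers)))
  pool <- NULL
  got <- 0L
  offset <- 0L
  while (got < n_pool) {
    f2 <- make_f2_population(batch_size, map, build)
    f2$individual <- f2$individual + offset
    offset <- offset + batch_size
    sel <- select_homozygous_mutants(f2, mutation_chrom, mutation_pos_bp,
                                     penetrance)
    pool <- dplyr::bind_rows(pool, sel)
    got <- length(unique(pool$individual))
  }
  keep <- sort(unique(pool$individual))[seq_len(n_pool)]
  pool <- pool[pool$individual %in% keep, ]
  fractions <- cb_allele_fractions(pool, markers)
  observations <- simulate_pool_bands(fractions)
  result <- call_pooled(observations, build)
  list(pool = pool, observations = observations, result = result)
}
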