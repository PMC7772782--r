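#' Simulate a complete synthetic iCLIP + knockdown RNA-seq study
#'
#' Runs the generator stages in order: genome and annotation, motif planting
#' with regulation assignment, crosslink tracks with surrogate significant
#' sites, and the paired cassette-exon PSI table. All randomness derives
#' from `config$seed`.
#'
#' @param config A [synth_config()].
#' @return List with `config`, `genome`, `annotation`, `catalog`,
#'   `tracks` (list: `replicates`, `merged`, `sites`) and `ce` (a
#'   `ce_events` table).
#' @export
simulate_study <- function(config = synth_config()) {
  ga <- generate_genome_and_annotation(config)
  pm <- plant_motifs(ga$genome, ga$annotation, config)
  tracks <- simulate_crosslink_data(ga$annotation, pm$catalog, config)
  ce <- simulate_ce_table(ga$annotation, pm$catalog, config)
  list(config = config, genome = pm$genome, annotation = ga$annotation,
       catalog = pm$catalog, tracks = tracks, ce = ce)
}

#' Chromosome lengths of a genome
#'
#' @param genome A `DNAStringSet`.
#' @return Named integer vector.
#' @export
chrom_lengths <- function(genome) {
  stats::setNames(Biostrings::width(genome), names(genome))
}
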