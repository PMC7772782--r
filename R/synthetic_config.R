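#' Configuration for the synthetic iCLIP study generator
#'
#' Bundles and validates all tunable parameters of the synthetic-data module.
#' The defaults describe the simulated study that the package's tests and the
#' analysis scripts run end-to-end: a few hundred multi-exon genes, four iCLIP
#' replicates with sparse overdispersed crosslink counts, GAA-repeat motifs
#' planted at regulated cassette exons, and a paired control/knockdown PSI
#' table with five replicate pairs.
#'
#' @param n_genes Number of genes to simulate.
#' @param exons_per_gene Inclusive range `c(lo, hi)` of exons per gene
#'   (at least 3, so every gene has a cassette exon with constitutive
#'   neighbours).
#' @param exon_len,intron_len Inclusive nt ranges for exon and intron lengths.
#' @param n_replicates Number of iCLIP replicates (default 4).
#' @param motif_repeat_range Inclusive range of consecutive GAA triplets
#'   planted per motif site.
#' @param background_rate Mean crosslink events per nucleotide per replicate
#'   outside planted signal.
#' @param enrichment_factor Fold-increase of the event rate over planted motif
#'   runs (ramped towards the 3' end of the run).
#' @param region_enrichment Fold-increase of the event rate across the
#'   regulated region of a regulated cassette-exon event: the alternative exon
#'   body for down-regulated events, the flanking constitutive exons for
#'   up-regulated events.
#' @param dispersion Negative-binomial `size` parameter of the count noise
#'   (smaller = more overdispersed).
#' @param ce_fraction_down,ce_fraction_up Fractions of cassette exons regulated
#'   down (less inclusion after knockdown) and up.
#' @param dpsi_effect Mean |dPSI| planted for regulated exons.
#' @param psi_concentration Beta concentration of the replicate PSI noise.
#' @param pair_sd SD of the shared per-replicate-pair PSI offset (paired
#'   design).
#' @param n_psi_replicates Paired control/KD replicates in the PSI table
#'   (default 5).
#' @param read_depth Mean junction reads per replicate per event.
#' @param low_depth_fraction Fraction of events simulated at low junction-read
#'   depth, to exercise the read filter.
#' @param noncoding_fraction Fraction of genes given a non-coding biotype.
#' @param neutral_site_rate Probability that an unregulated gene carries a
#'   neutral planted motif site.
#' @param background_quantile Per-gene count quantile above which the surrogate
#'   caller reports a significant crosslink site.
#' @param genes_per_chrom Genes placed per simulated chromosome.
#' @param seed Master integer seed; all sub-streams derive from it.
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(n_genes = 300,
                         exons_per_gene = c(3, 8),
                         exon_len = c(80, 250),
                         intron_len = c(150, 500),
                         n_replicates = 4,
                         motif_repeat_range = c(2, 6),
                         background_rate = 0.15,
                         enrichment_factor = 12,
                         region_enrichment = 5,
                         dispersion = 0.5,
                         ce_fraction_down = 0.08,
                         ce_fraction_up = 0.04,
                         dpsi_effect = 0.2,
                         psi_concentration = 300,
                         pair_sd = 0.03,
                         n_psi_replicates = 5,
                         read_depth = 60,
                         low_depth_fraction = 0.05,
                         noncoding_fraction = 0.1,
                         neutral_site_rate = 0.3,
                         background_quantile = 0.99,
                         genes_per_chrom = 25,
                         seed = 1) {
  cfg <- list(
    n_genes = as.integer(n_genes), exons_per_gene = exons_per_gene,
    exon_len = exon_len, intron_len = intron_len,
    n_replicates = as.integer(n_replicates),
    motif_repeat_range = motif_repeat_range,
    background_rate = background_rate,
    enrichment_factor = enrichment_factor,
    region_enrichment = region_enrichment,
    dispersion = dispersion,
    ce_fraction_down = ce_fraction_down, ce_fraction_up = ce_fraction_up,
    dpsi_effect = dpsi_effect, psi_concentration = psi_concentration,
    pair_sd = pair_sd, n_psi_replicates = as.integer(n_psi_replicates),
    read_depth = read_depth, low_depth_fraction = low_depth_fraction,
    noncoding_fraction = noncoding_fraction,
    neutral_site_rate = neutral_site_rate,
    background_quantile = background_quantile,
    genes_per_chrom = as.integer(genes_per_chrom),
    seed = as.integer(seed)
  )
  validate_synth_config(cfg)
  structure(cfg, class = "synth_config")
}

validate_synth_config <- function(cfg) {
  if (cfg$n_genes < 0) stopf("n_genes must be >= 0")
  check_range(cfg$exons_per_gene, "exons_per_gene")
  if (cfg$exons_per_gene[1] < 3)
    stopf("exons_per_gene must start at >= 3 (cassette exon needs neighbours)")
  check_range(cfg$exon_len, "exon_len")
  check_range(cfg$intron_len, "intron_len")
  check_range(cfg$motif_repeat_range, "motif_repeat_range")
  if (cfg$motif_repeat_range[1] < 1) stopf("motif_repeat_range must be >= 1")
  if (cfg$exon_len[1] < 20) stopf("exon_len must be >= 20 nt")
  for (f in c("background_rate", "enrichment_factor", "region_enrichment",
              "dispersion", "psi_concentration", "read_depth"))
    if (cfg[[f]] <= 0) stopf("'%s' must be > 0", f)
  fr <- c(cfg$ce_fraction_down, cfg$ce_fraction_up)
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1)
    stopf("cassette-exon fractions must lie in [0,1] and sum to <= 1")
  if (cfg$dpsi_effect < 0 || cfg$dpsi_effect > 1)
    stopf("dpsi_effect must lie in [0,1]")
  if (cfg$background_quantile <= 0 || cfg$background_quantile >= 1)
    stopf("background_quantile must lie in (0,1)")
  if (cfg$n_replicates < 1 || cfg$n_psi_replicates < 2)
    stopf("need >= 1 iCLIP replicate and >= 2 PSI replicate pairs")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("synthetic iCLIP study configuration\n")
  cat(sprintf("  genes: %d (%d-%d exons), %d iCLIP replicates, seed %d\n",
              x$n_genes, x$exons_per_gene[1], x$exons_per_gene[2],
              x$n_replicates, x$seed))
  cat(sprintf("  counts: NB(mu=%.3g/nt, size=%.3g), motif x%.3g, region x%.3g\n",
              x$background_rate, x$dispersion, x$enrichment_factor,
              x$region_enrichment))
  cat(sprintf("  cassette exons: %.0f%% down / %.0f%% up, |dPSI| ~ %.2f\n",
              100 * x$ce_fraction_down, 100 * x$ce_fraction_up, x$dpsi_effect))
  invisible(x)
}
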