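#!/usr/bin/env Rscript
# Generate the synthetic iCLIP + knockdown study all later steps analyse:
# genome FASTA, GENCODE-dialect GTF, per-replicate and merged bedGraph
# crosslink tracks, surrogate-caller significant sites (BED) and the
# rMATS-style cassette-exon table, plus the planted-motif ground truth.

library(clipmap)

seed <- as.integer(Sys.getenv("CLIPMAP_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- synth_config(seed = seed)
print(cfg)
st <- simulate_study(cfg)

Biostrings::writeXStringSet(st$genome, file.path(out, "genome.fa"))
write_gtf(st$annotation, file.path(out, "annotation.gtf"))
for (r in seq_along(st$tracks$replicates))
  write_track_bedgraph(st$tracks$replicates[[r]],
                       file.path(out, sprintf("xlinks_rep%d", r)))
write_track_bedgraph(st$tracks$merged, file.path(out, "xlinks_merged"))
write_sig_sites_bed(st$tracks$sites, file.path(out, "sig_sites.bed"))
write_ce_table(st$ce, file.path(out, "cassette_exons.tsv"))
utils::write.table(st$catalog$sites, file.path(out, "planted_sites.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
utils::write.table(st$catalog$genes, file.path(out, "planted_genes.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

message(sprintf(
  "simulated %d genes on %d chromosomes: %d planted motif sites, %d significant crosslink positions, %d cassette-exon events (%d down / %d up planted)",
  cfg$n_genes, length(st$genome), nrow(st$catalog$sites),
  nrow(st$tracks$sites), nrow(st$ce),
  sum(st$catalog$genes$class == "down"),
  sum(st$catalog$genes$class == "up")))
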