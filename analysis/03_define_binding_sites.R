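#!/usr/bin/env Rscript
# Define reproducible 9-nt binding sites from the significant crosslink
# sites and the replicate/merged crosslink tracks written by 01: score
# filter, <8-nt clustering, summit-centered extension/splitting with >= 2
# significant positions, and the 3-of-4 replicate support filter at the
# per-replicate 20% count quantile.

library(clipmap)

data_dir <- "results/data"
out <- "results/binding_sites"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

sites <- read_sig_sites_bed(file.path(data_dir, "sig_sites.bed"))
merged <- read_track_bedgraph(file.path(data_dir, "xlinks_merged"))
reps <- lapply(1:4, function(r)
  read_track_bedgraph(file.path(data_dir, sprintf("xlinks_rep%d", r)),
                      replicate = paste0("rep", r)))
genome <- Biostrings::readDNAStringSet(file.path(data_dir, "genome.fa"))

kept <- filter_low_scores(sites)
regions <- cluster_sites(kept)
bs0 <- define_binding_sites(regions, merged, kept,
                            chrom_lengths = chrom_lengths(genome))
bs <- reproducibility_filter(bs0, reps)
write_binding_sites(bs, file.path(out, "binding_sites"))

message(sprintf(
  "%d significant sites -> %d after 5%% score filter -> %d regions -> %d candidate sites -> %d reproducible binding sites (median strength %.2f)",
  nrow(sites), nrow(kept), nrow(regions), nrow(bs0), nrow(bs),
  stats::median(bs$strength)))
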