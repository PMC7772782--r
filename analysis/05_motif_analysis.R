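#!/usr/bin/env Rscript
# Motif analytics around the binding sites: pentamer counts in the site and
# its 20-nt flanks per region class, 201-nt positional profiles with 3-way
# k-means clustering, GAA/UUC triplet counts versus site strength in 49-nt
# windows, and consecutive-triplet run classes.

library(clipmap)

seed <- as.integer(Sys.getenv("CLIPMAP_SEED", "1"))
out <- "results/motifs"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

genome <- Biostrings::readDNAStringSet("results/data/genome.fa")
assigned <- utils::read.table("results/annotation/assignments.tsv",
                              sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
assigned <- assigned[!is.na(assigned$region), ]

samp <- sample_sites(assigned, per_region_n = 5000, seed = seed)
pw <- pentamer_window_counts(samp, genome)
pw$pentamer <- to_rna(pw$pentamer)
utils::write.table(pw, file.path(out, "pentamer_window_counts.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
top_cds <- pw[pw$region == "CDS", ]
top_cds <- top_cds[order(-top_cds$site_mean), ][1:5, ]
message(sprintf("top CDS pentamers in sites: %s",
                paste(sprintf("%s (%.2f)", top_cds$pentamer,
                              top_cds$site_mean), collapse = ", ")))

prof <- positional_profiles(samp, genome)
long <- data.frame(pentamer = to_rna(rep(rownames(prof), ncol(prof))),
                   offset = rep(as.integer(colnames(prof)),
                                each = nrow(prof)),
                   frequency = as.vector(prof))
utils::write.table(long[long$frequency > 0, ],
                   file.path(out, "positional_profiles.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

cds_freq <- stats::setNames(pw$site_mean[pw$region == "CDS"],
                            chartr("U", "T", pw$pentamer[pw$region == "CDS"]))
n_top <- min(300, sum(cds_freq > 0))
cl <- cluster_profiles(prof, cds_freq, k = 3, top_n = n_top, seed = seed)
cl$pentamer <- to_rna(cl$pentamer)
utils::write.table(cl, file.path(out, "profile_clusters.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("profile clustering of top %d pentamers: sizes %s", n_top,
                paste(table(cl$cluster), collapse = "/")))

ts <- triplet_strength_analysis(assigned, genome)
utils::write.table(ts, file.path(out, "triplet_counts.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
for (tr in c("n_GAA", "n_UUC")) {
  s <- summarize_triplet_strength(ts, tr)
  utils::write.table(s, file.path(out, paste0("strength_by_", tr, ".tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}
runs <- consecutive_run_analysis(assigned, genome)
utils::write.table(runs, file.path(out, "triplet_runs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
message(sprintf("triplet run classes: %s",
                paste(names(table(runs$class)), table(runs$class),
                      collapse = ", ")))
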