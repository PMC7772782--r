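#!/usr/bin/env Rscript
# Filter the rMATS-style cassette-exon table into regulated sets
# (FDR < 0.05, |dPSI| > 0.05, log2 mean junction reads > 5) and annotate
# each regulated event with the binding sites inside its alternatively
# spliced region (donor of the upstream exon -100 nt to acceptor of the
# downstream exon +100 nt).

library(clipmap)

out <- "results/splicing"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ce <- read_ce_table("results/data/cassette_exons.tsv")
bs <- utils::read.table("results/binding_sites/binding_sites.tsv",
                        sep = "\t", header = TRUE, stringsAsFactors = FALSE)

sets <- filter_significant_events(ce)
print(sets)
for (nm in c("down", "up")) {
  ov <- as_region_overlap(sets[[nm]], bs)
  utils::write.table(ov, file.path(out, paste0(nm, "_events.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  message(sprintf(
    "%s-regulated: %d events, %d (%.0f%%) with >= 1 binding site in the AS region; strongest site strength median %.2f",
    nm, nrow(ov), sum(ov$n_sites_as_region > 0),
    100 * mean(ov$n_sites_as_region > 0),
    stats::median(ov$max_site_strength, na.rm = TRUE)))
}
utils::write.table(sets$unchanged, file.path(out, "unchanged_events.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
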