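#!/usr/bin/env Rscript
# Assign binding sites to genes and transcript regions: GENCODE-style
# support filters, unique protein-coding gene rule, majority vote with the
# intron > CDS > 3'UTR > 5'UTR hierarchy, length-normalized densities and
# the gene-biotype distribution.

library(clipmap)

out <- "results/annotation"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ann <- load_annotation("results/data/annotation.gtf")
bs <- utils::read.table("results/binding_sites/binding_sites.tsv",
                        sep = "\t", header = TRUE, stringsAsFactors = FALSE)

assigned <- assign_region(assign_unique_gene(bs, ann), ann)
utils::write.table(assigned, file.path(out, "assignments.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

dens <- region_enrichment(assigned, ann)
utils::write.table(dens, file.path(out, "region_density.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
bt <- gene_type_distribution(bs, ann)
utils::write.table(bt, file.path(out, "gene_biotypes.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

ok <- !is.na(assigned$region)
message(sprintf(
  "%d / %d sites uniquely assigned; region counts: %s; per-kb densities: %s",
  sum(ok), nrow(assigned),
  paste(names(table(assigned$region[ok])), table(assigned$region[ok]),
        collapse = ", "),
  paste(dens$region, round(dens$sites_per_kb, 2), collapse = ", ")))
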