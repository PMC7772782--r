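#!/usr/bin/env Rscript
# Read-level preprocessing demonstration: simulate a raw multiplexed iCLIP
# lane, then apply the barcode quality filter, exact-match demultiplexing,
# adapter trimming and the 15-nt length filter; finally deduplicate a set
# of aligned read stubs on the random barcode.

library(clipmap)

seed <- as.integer(Sys.getenv("CLIPMAP_SEED", "1"))
out <- "results/preprocess"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

barcodes <- c(iCLIP_rep1 = "GGTT", iCLIP_rep2 = "ACCA",
              iCLIP_rep3 = "TCGA", iCLIP_rep4 = "CATG")
reads <- simulate_iclip_reads(barcodes, n_reads = 5000, seed = seed,
                              adapter_fraction = 0.4,
                              unassigned_fraction = 0.05)
write_fastq(reads, file.path(out, "raw.fastq"))

res <- preprocess_reads(read_fastq(file.path(out, "raw.fastq")), barcodes)
for (s in names(res$samples))
  write_fastq(res$samples[[s]], file.path(out, paste0(s, ".fastq")))
utils::write.table(res$summary, file.path(out, "summary.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)

message(sprintf(
  "%d raw reads: %d dropped on barcode quality, %d undetermined, %d kept after trimming and length filter",
  nrow(reads), nrow(res$dropped), nrow(res$undetermined),
  sum(res$summary$kept)))

# UMI deduplication on synthetic aligned stubs: duplicates share a 5'-end
# position; identical random barcodes are collapsed
set.seed(seed)
stubs <- data.frame(chrom = "chr1", strand = "+",
                    pos = sample(1:500, 2000, replace = TRUE),
                    umi = replicate(2000, paste(sample(c("A", "C", "G", "T"),
                                                       5, TRUE),
                                                collapse = "")))
kept <- dedup_random_barcode(stubs)
message(sprintf("UMI dedup: %d stubs -> %d distinct molecules", nrow(stubs),
                nrow(kept)))
utils::write.table(kept, file.path(out, "dedup_stubs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
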