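#' Read-level preprocessing rules for iCLIP libraries
#'
#' Implements the barcode-region quality filter, no-mismatch demultiplexing
#' with barcode transfer to the read name, suffix adapter trimming, the
#' post-trimming length filter, and random-barcode (UMI) deduplication of
#' aligned read stubs. Reads are plain data.frames with columns `id`, `seq`
#' and `qual` (Phred+33 by default); every transformation preserves the
#' equality of sequence and quality lengths.
#'
#' @name read_preprocessing
NULL

phred_ints <- function(qual, offset = 33L) {
  lapply(qual, function(q) utf8ToInt(q) - offset)
}

#' Filter reads on barcode-region sequencing quality
#'
#' A read is dropped when more than `max_low_sample` sample-barcode positions
#' (default positions 4-7) have quality below `q_sample` (20), or when any
#' random-barcode position (1-3 and 8-9) has quality below `q_random` (17).
#' Both comparisons are strict.
#'
#' @param reads Read data.frame (`id`, `seq`, `qual`).
#' @param sample_pos,random_pos 1-based barcode position sets.
#' @param q_sample,q_random Phred thresholds.
#' @param max_low_sample Allowed sub-threshold sample-barcode positions.
#' @param offset Phred encoding offset (33 = Sanger).
#' @return List with `kept` (read data.frame) and `dropped` (data.frame of
#'   `id`, `reason`).
#' @export
filter_barcode_quality <- function(reads, sample_pos = 4:7,
                                   random_pos = c(1:3, 8:9),
                                   q_sample = 20, q_random = 17,
                                   max_low_sample = 1, offset = 33L) {
  need <- max(sample_pos, random_pos)
  if (any(nchar(reads$seq) < need))
    stopf("malformed read(s): shorter than the %d-nt barcode region", need)
  qs <- phred_ints(reads$qual, offset)
  low_sample <- vapply(qs, function(q) sum(q[sample_pos] < q_sample), 0L)
  low_random <- vapply(qs, function(q) any(q[random_pos] < q_random), NA)
  drop <- low_sample > max_low_sample | low_random
  reason <- ifelse(low_sample > max_low_sample & low_random,
                   "sample+random barcode quality",
            ifelse(low_sample > max_low_sample, "sample barcode quality",
                   "random barcode quality"))
  list(kept = reads[!drop, , drop = FALSE],
       dropped = data.frame(id = reads$id[drop], reason = reason[drop],
                            stringsAsFactors = FALSE))
}

#' Demultiplex reads on the sample barcode with no mismatches
#'
#' The 4-mer at `sample_pos` must equal a table barcode exactly; anything
#' else lands in the `undetermined` bin. The whole `barcode_len`-nt barcode
#' region is trimmed off sequence and qualities and appended to the read
#' identifier so the random barcode stays available downstream.
#'
#' @param reads Read data.frame.
#' @param barcodes Named character vector of sample barcodes.
#' @param sample_pos Positions of the sample barcode within the read.
#' @param barcode_len Total barcode-region length trimmed from the 5' end.
#' @return Named list of read data.frames (one per sample, plus
#'   `undetermined`).
#' @export
demultiplex <- function(reads, barcodes, sample_pos = 4:7, barcode_len = 9L) {
  stopifnot(length(unique(nchar(barcodes))) <= 1L,
            !anyDuplicated(barcodes))
  bc <- substr(reads$seq, min(sample_pos), max(sample_pos))
  assigned <- names(barcodes)[match(bc, barcodes)]
  assigned[is.na(assigned)] <- "undetermined"
  full_bc <- substr(reads$seq, 1L, barcode_len)
  out <- reads
  out$id <- paste0(out$id, "_", full_bc)
  out$seq <- substring(out$seq, barcode_len + 1L)
  out$qual <- substring(out$qual, barcode_len + 1L)
  out$umi <- paste0(substr(full_bc, 1L, 3L), substr(full_bc, 8L, 9L))
  split(out, factor(assigned, levels = unique(c(names(barcodes),
                                                "undetermined"))))
}

#' Trim a 3' adapter from reads
#'
#' Finds the longest read suffix matching a prefix of the adapter with at
#' most one mismatch per 10 nt of overlap (`floor(overlap/10)`), requiring at
#' least `min_overlap` nt; the matched suffix is removed from sequence and
#' qualities. Ties in acceptability are broken toward the longer trim; reads
#' without any acceptable overlap are returned unchanged.
#'
#' @param reads Read data.frame.
#' @param adapter Adapter sequence.
#' @param min_overlap Minimum read/adapter overlap in nt.
#' @param mismatch_per_nt One mismatch allowed per this many nt of overlap.
#' @return The reads with adapter suffixes removed.
#' @export
trim_adapter <- function(reads, adapter = "AGATCGGAAGAGCGGTTCAG",
                         min_overlap = 1L, mismatch_per_nt = 10L) {
  ad <- strsplit(adapter, "")[[1]]
  trim_len <- vapply(reads$seq, function(s) {
    n <- nchar(s)
    sv <- strsplit(s, "")[[1]]
    for (L in seq.int(min(n, length(ad)), min_overlap)) {
      mm <- sum(sv[(n - L + 1L):n] != ad[seq_len(L)])
      if (mm <= L %/% mismatch_per_nt) return(L)
    }
    0L
  }, 0L, USE.NAMES = FALSE)
  n <- nchar(reads$seq)
  reads$seq <- substr(reads$seq, 1L, n - trim_len)
  reads$qual <- substr(reads$qual, 1L, n - trim_len)
  reads
}

#' Drop reads shorter than a minimum length
#'
#' @param reads Read data.frame (after barcode and adapter trimming).
#' @param min_len Minimum kept length in nt (default 15).
#' @return The kept reads.
#' @export
length_filter <- function(reads, min_len = 15L) {
  reads[nchar(reads$seq) >= min_len, , drop = FALSE]
}

#' Deduplicate aligned read stubs on the random barcode
#'
#' Within each duplicate group -- reads sharing chromosome, strand and 5'-end
#' position -- exactly one representative per distinct random-barcode string
#' is retained: identical barcodes are technical (PCR) duplicates, distinct
#' barcodes are independent molecules.
#'
#' @param stubs Data.frame with `chrom`, `strand`, `pos` (5'-end position)
#'   and `umi` (random-barcode string).
#' @return The retained stubs.
#' @export
dedup_random_barcode <- function(stubs) {
  stubs[!duplicated(paste(stubs$chrom, stubs$strand, stubs$pos, stubs$umi,
                          sep = "\r")), , drop = FALSE]
}

#' Run the full read-preprocessing chain
#'
#' Quality filter, then demultiplexing (barcode to the read name), then
#' adapter trimming, then the length filter, per sample.
#'
#' @param reads Read data.frame.
#' @param barcodes Named character vector of sample barcodes.
#' @param min_len Minimum post-trimming read length.
#' @param adapter Adapter sequence.
#' @return List with `samples` (named list of read data.frames),
#'   `undetermined`, `dropped` (quality-filter casualties) and `summary`
#'   (per-sample reads in/out).
#' @export
preprocess_reads <- function(reads, barcodes, min_len = 15L,
                             adapter = "AGATCGGAAGAGCGGTTCAG") {
  qf <- filter_barcode_quality(reads)
  bins <- demultiplex(qf$kept, barcodes)
  undet <- bins$undetermined
  bins <- bins[setdiff(names(bins), "undetermined")]
  samples <- lapply(bins, function(b)
    length_filter(trim_adapter(b, adapter), min_len))
  summary <- data.frame(
    sample = names(bins),
    demultiplexed = vapply(bins, nrow, 0L),
    kept = vapply(samples, nrow, 0L), row.names = NULL,
    stringsAsFactors = FALSE)
  list(samples = samples, undetermined = undet, dropped = qf$dropped,
       summary = summary)
}
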