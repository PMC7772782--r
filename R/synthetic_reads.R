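#' Simulate raw iCLIP reads
#'
#' Reads follow the experimental barcode layout: a 3-nt random barcode,
#' a 4-nt sample barcode, a 2-nt random barcode, then the cDNA insert, and in
#' a configurable fraction of reads a (possibly truncated) prefix of the
#' sequencing adapter at the 3' end. Qualities default to a constant Phred
#' score; tests construct reads with hand-set qualities directly to exercise
#' the filter branches.
#'
#' @param barcodes Named character vector of 4-nt sample barcodes.
#' @param n_reads Number of reads.
#' @param seed Integer seed.
#' @param insert_len Inclusive range of insert lengths.
#' @param adapter Adapter sequence appended (possibly truncated).
#' @param adapter_fraction Fraction of reads carrying adapter sequence.
#' @param full_adapter_fraction Among adapter-carrying reads, fraction with
#'   the full-length adapter (the rest get a random-length prefix).
#' @param unassigned_fraction Fraction of reads given a sample barcode not in
#'   the table (demultiplexing "undetermined" bin).
#' @param base_quality Constant Phred quality for all bases.
#' @return A data.frame of reads (`id`, `seq`, `qual`) with ground-truth
#'   columns `sample` (`NA` for unassigned) and `umi` (the 5-nt random
#'   barcode).
#' @export
simulate_iclip_reads <- function(barcodes, n_reads, seed = 1,
                                 insert_len = c(20, 40),
                                 adapter = "AGATCGGAAGAGCGGTTCAG",
                                 adapter_fraction = 0.3,
                                 full_adapter_fraction = 0.5,
                                 unassigned_fraction = 0.05,
                                 base_quality = 35) {
  stopifnot(all(nchar(barcodes) == 4L), !is.null(names(barcodes)))
  if (n_reads == 0L)
    return(data.frame(id = character(), seq = character(), qual = character(),
                      sample = character(), umi = character(),
                      stringsAsFactors = FALSE))
  with_seed(seed, {
    rand_nt <- function(n) vapply(n, function(k)
      paste(sample(c("A", "C", "G", "T"), k, replace = TRUE), collapse = ""),
      character(1))
    sample_of <- sample(names(barcodes), n_reads, replace = TRUE)
    bc <- unname(barcodes[sample_of])
    unassigned <- stats::runif(n_reads) < unassigned_fraction
    for (i in which(unassigned)) {
      repeat {
        alt <- rand_nt(4L)
        if (!alt %in% barcodes) break
      }
      bc[i] <- alt
      sample_of[i] <- NA_character_
    }
    umi1 <- rand_nt(rep(3L, n_reads))
    umi2 <- rand_nt(rep(2L, n_reads))
    ins <- rand_nt(sample_range(insert_len, n_reads))
    ad <- character(n_reads)
    has_ad <- stats::runif(n_reads) < adapter_fraction
    full <- has_ad & stats::runif(n_reads) < full_adapter_fraction
    ad[full] <- adapter
    part <- has_ad & !full
    ad[part] <- substr(rep(adapter, sum(part)), 1L,
                       sample.int(nchar(adapter), sum(part), replace = TRUE))
    seqs <- paste0(umi1, bc, umi2, ins, ad)
    data.frame(id = sprintf("read%06d", seq_len(n_reads)), seq = seqs,
               qual = strrep(intToUtf8(base_quality + 33L), nchar(seqs)),
               sample = sample_of, umi = paste0(umi1, umi2),
               stringsAsFactors = FALSE)
  })
}

#' Write / read FASTQ (via Biostrings)
#'
#' @param reads Read data.frame with `id`, `seq`, `qual`.
#' @param path FASTQ path.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$seq)
  names(x) <- reads$id
  Biostrings::writeXStringSet(
    x, path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  data.frame(id = names(x), seq = as.character(x),
             qual = as.character(S4Vectors::mcols(x)$qualities),
             stringsAsFactors = FALSE)
}
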