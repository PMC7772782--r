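#' Generate a synthetic genome and transcript annotation
#'
#' Builds a random genome (uniform base composition) and a matching
#' multi-exon gene annotation. Every gene carries one transcript with at
#' least three exons; a middle exon is designated as the gene's cassette
#' exon and recorded in the gene table (generator ground truth; not part of
#' the GTF representation). Protein-coding transcripts get a CDS flanked by
#' 5' and 3' UTR parts so that all four transcript regions exist.
#'
#' @param config A [synth_config()].
#' @return A list with `genome` (a [Biostrings::DNAStringSet]) and
#'   `annotation` (a `transcript_annotation` object; see [load_annotation()]).
#' @export
generate_genome_and_annotation <- function(config) {
  validate_synth_config(config)
  n <- config$n_genes
  if (n == 0L) {
    return(list(genome = Biostrings::DNAStringSet(),
                annotation = empty_annotation()))
  }
  with_seed(substream_seed(config$seed, 0L, "genome"), {
    k <- sample_range(config$exons_per_gene, n)
    genes <- vector("list", n)
    exons <- vector("list", n)
    cdss <- vector("list", n)
    gene_type <- ifelse(stats::runif(n) < config$noncoding_fraction,
                        "lncRNA", "protein_coding")
    level <- sample(c(1L, 2L, 3L), n, replace = TRUE, prob = c(.45, .45, .10))
    tsl <- sample(c("1", "2", "3", "4", "NA"), n, replace = TRUE,
                  prob = c(.35, .30, .20, .10, .05))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    chrom <- paste0("chr", ceiling(seq_len(n) / config$genes_per_chrom))
    cursor <- integer(0)  # per-chromosome layout cursor

    for (i in seq_len(n)) {
      el <- sample_range(config$exon_len, k[i])
      il <- sample_range(config$intron_len, k[i] - 1L)
      glen <- sum(el) + sum(il)
      cur <- if (is.na(cursor[chrom[i]])) 0L else cursor[chrom[i]]
      gstart <- cur + sample(200:600, 1L)
      cursor[chrom[i]] <- gstart + glen - 1L
      # genomic exon coordinates (1-based closed), left to right
      estart <- gstart + cumsum(c(0L, el[-k[i]] + il))
      eend <- estart + el - 1L
      gid <- sprintf("SYNG%05d", i)
      tid <- sprintf("SYNT%05d", i)
      alt <- if (k[i] == 3L) 2L else sample(2:(k[i] - 1L), 1L)
      exons[[i]] <- data.frame(
        transcript_id = tid, gene_id = gid, exon_number = seq_len(k[i]),
        chrom = chrom[i], start = estart, end = eend, strand = strand[i],
        stringsAsFactors = FALSE)
      if (gene_type[i] == "protein_coding") {
        cdss[[i]] <- make_cds(exons[[i]], strand[i])
      }
      genes[[i]] <- data.frame(
        gene_id = gid, transcript_id = tid, chrom = chrom[i],
        start = gstart, end = gstart + glen - 1L, strand = strand[i],
        gene_type = gene_type[i], level = level[i], tsl = tsl[i],
        n_exons = k[i], alt_exon_number = alt, stringsAsFactors = FALSE)
    }
    genes <- do.call(rbind, genes)
    exons <- do.call(rbind, exons)
    cds <- if (length(Filter(Negate(is.null), cdss)))
      do.call(rbind, Filter(Negate(is.null), cdss)) else empty_cds()
    transcripts <- data.frame(
      transcript_id = genes$transcript_id, gene_id = genes$gene_id,
      chrom = genes$chrom, start = genes$start, end = genes$end,
      strand = genes$strand, tsl = genes$tsl, stringsAsFactors = FALSE)

    chrom_len <- tapply(genes$end + 300L, genes$chrom, max)
    seqs <- vapply(names(chrom_len), function(cn) {
      paste(sample(c("A", "C", "G", "T"), chrom_len[[cn]], replace = TRUE),
            collapse = "")
    }, character(1))
    genome <- Biostrings::DNAStringSet(seqs)

    ann <- new_annotation(genes, transcripts, exons, cds)
    list(genome = genome, annotation = ann)
  })
}

# CDS for one transcript: 5'/3' UTR lengths carved from the terminal exons
# (transcript orientation), CDS length trimmed to a codon multiple.
make_cds <- function(ex, strand) {
  el <- ex$end - ex$start + 1L
  L <- sum(el)
  first_len <- if (strand == "+") el[1] else el[nrow(ex)]
  last_len <- if (strand == "+") el[nrow(ex)] else el[1]
  utr5 <- max(12L, round(0.35 * first_len))
  utr3 <- max(12L, round(0.35 * last_len))
  cds_len <- L - utr5 - utr3
  cds_len <- cds_len - (cds_len %% 3L)
  stopifnot(cds_len >= 30L)
  tx <- transcript_to_genomic(utr5 + 1L, utr5 + cds_len, ex, strand)
  data.frame(transcript_id = ex$transcript_id[1], chrom = ex$chrom[1],
             start = tx$start, end = tx$end, strand = strand,
             stringsAsFactors = FALSE)
}

# Map a contiguous transcript-coordinate interval [t1, t2] (1-based, 5'->3')
# onto genomic intervals, one row per exon touched.
transcript_to_genomic <- function(t1, t2, ex, strand) {
  ord <- if (strand == "+") order(ex$start) else order(-ex$start)
  ex <- ex[ord, , drop = FALSE]
  el <- ex$end - ex$start + 1L
  offs <- cumsum(c(0L, el[-length(el)]))  # transcript offset of each exon
  out <- list()
  for (j in seq_len(nrow(ex))) {
    a <- max(t1, offs[j] + 1L)
    b <- min(t2, offs[j] + el[j])
    if (a > b) next
    if (strand == "+") {
      gs <- ex$start[j] + (a - offs[j] - 1L)
      ge <- ex$start[j] + (b - offs[j] - 1L)
    } else {
      ge <- ex$end[j] - (a - offs[j] - 1L)
      gs <- ex$end[j] - (b - offs[j] - 1L)
    }
    out[[length(out) + 1L]] <- data.frame(start = gs, end = ge)
  }
  do.call(rbind, out)
}

empty_cds <- function() {
  data.frame(transcript_id = character(), chrom = character(),
             start = integer(), end = integer(), strand = character(),
             stringsAsFactors = FALSE)
}

empty_annotation <- function() {
  g <- data.frame(gene_id = character(), transcript_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), gene_type = character(),
                  level = integer(), tsl = character(), n_exons = integer(),
                  alt_exon_number = integer(), stringsAsFactors = FALSE)
  t <- data.frame(transcript_id = character(), gene_id = character(),
                  chrom = character(), start = integer(), end = integer(),
                  strand = character(), tsl = character(),
                  stringsAsFactors = FALSE)
  e <- data.frame(transcript_id = character(), gene_id = character(),
                  exon_number = integer(), chrom = character(),
                  start = integer(), end = integer(), strand = character(),
                  stringsAsFactors = FALSE)
  new_annotation(g, t, e, empty_cds())
}

new_annotation <- function(genes, transcripts, exons, cds) {
  structure(list(genes = genes, transcripts = transcripts, exons = exons,
                 cds = cds,
                 regions = derive_all_regions(transcripts, exons, cds)),
            class = "transcript_annotation")
}

#' @export
print.transcript_annotation <- function(x, ...) {
  cat(sprintf(
    "transcript annotation: %d genes, %d transcripts, %d exons, %d region intervals\n",
    nrow(x$genes), nrow(x$transcripts), nrow(x$exons), nrow(x$regions)))
  invisible(x)
}

# Derive intron/CDS/UTR5/UTR3 (or plain exon for non-coding transcripts)
# intervals for every transcript. Regions tile the transcript span.
derive_all_regions <- function(transcripts, exons, cds) {
  if (nrow(transcripts) == 0L)
    return(data.frame(transcript_id = character(), gene_id = character(),
                      chrom = character(), start = integer(), end = integer(),
                      strand = character(), region = character(),
                      stringsAsFactors = FALSE))
  ex_by_tx <- split(exons, exons$transcript_id)
  cds_by_tx <- split(cds, cds$transcript_id)
  out <- lapply(transcripts$transcript_id, function(tid) {
    ex <- ex_by_tx[[tid]]
    ex <- ex[order(ex$start), , drop = FALSE]
    derive_transcript_regions(ex, cds_by_tx[[tid]])
  })
  do.call(rbind, out)
}

derive_transcript_regions <- function(ex, cds) {
  strand <- ex$strand[1]
  rows <- list()
  add <- function(s, e, lab) {
    if (length(s) && any(s <= e))
      rows[[length(rows) + 1L]] <<- data.frame(
        transcript_id = ex$transcript_id[1], gene_id = ex$gene_id[1],
        chrom = ex$chrom[1], start = s[s <= e], end = e[s <= e],
        strand = strand, region = lab, stringsAsFactors = FALSE)
  }
  if (nrow(ex) > 1L)
    add(ex$end[-nrow(ex)] + 1L, ex$start[-1L] - 1L, "intron")
  if (is.null(cds) || nrow(cds) == 0L) {
    add(ex$start, ex$end, "exon")
  } else {
    cs <- min(cds$start); ce <- max(cds$end)
    left_lab <- if (strand == "+") "UTR5" else "UTR3"
    right_lab <- if (strand == "+") "UTR3" else "UTR5"
    for (j in seq_len(nrow(ex))) {
      s <- ex$start[j]; e <- ex$end[j]
      if (e < cs) add(s, e, left_lab)
      else if (s > ce) add(s, e, right_lab)
      else {
        if (s < cs) add(s, cs - 1L, left_lab)
        add(max(s, cs), min(e, ce), "CDS")
        if (e > ce) add(ce + 1L, e, right_lab)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else NULL
}
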