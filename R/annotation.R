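#' Load a GENCODE-dialect GTF as a filtered transcript annotation
#'
#' Imports gene/transcript/exon/CDS records (via rtracklayer), applies the
#' annotation support filters -- genes with `level` > 2 removed, transcripts
#' with `transcript_support_level` > 3 or non-numeric removed -- and derives
#' per-transcript region intervals (intron, CDS, 5'UTR, 3'UTR; plain `exon`
#' for transcripts without CDS). Regions tile each transcript span.
#'
#' @param path GTF file path.
#' @param max_gene_level Maximum GENCODE annotation level kept (default 2).
#' @param max_tsl Maximum transcript support level kept (default 3).
#' @return A `transcript_annotation` object (lists `genes`, `transcripts`,
#'   `exons`, `cds`, `regions`; 1-based closed coordinates).
#' @export
load_annotation <- function(path, max_gene_level = 2, max_tsl = 3) {
  gr <- tryCatch(rtracklayer::import(path, format = "gtf"),
                 error = function(e) stopf("GTF parse error in '%s': %s",
                                           path, conditionMessage(e)))
  df <- as.data.frame(gr, stringsAsFactors = FALSE)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  if (is.null(df$level)) df$level <- "1"
  if (is.null(df$transcript_support_level)) df$transcript_support_level <- "1"
  if (is.null(df$gene_type)) df$gene_type <- "protein_coding"
  lvl <- suppressWarnings(as.integer(df$level))

  g <- df[df$type == "gene", , drop = FALSE]
  keep_genes <- g$gene_id[!is.na(lvl[df$type == "gene"]) &
                            lvl[df$type == "gene"] <= max_gene_level]
  g <- g[g$gene_id %in% keep_genes, , drop = FALSE]

  t <- df[df$type == "transcript" & df$gene_id %in% keep_genes, , drop = FALSE]
  tsl <- suppressWarnings(as.integer(t$transcript_support_level))
  t <- t[!is.na(tsl) & tsl <= max_tsl, , drop = FALSE]
  keep_tx <- t$transcript_id

  e <- df[df$type == "exon" & df$transcript_id %in% keep_tx, , drop = FALSE]
  cc <- df[df$type == "CDS" & df$transcript_id %in% keep_tx, , drop = FALSE]

  genes <- data.frame(gene_id = g$gene_id,
                      transcript_id = NA_character_,
                      chrom = g$seqnames, start = g$start, end = g$end,
                      strand = g$strand, gene_type = g$gene_type,
                      level = suppressWarnings(as.integer(g$level)),
                      tsl = NA_character_,
                      n_exons = NA_integer_, alt_exon_number = NA_integer_,
                      stringsAsFactors = FALSE)
  transcripts <- data.frame(transcript_id = t$transcript_id,
                            gene_id = t$gene_id, chrom = t$seqnames,
                            start = t$start, end = t$end, strand = t$strand,
                            tsl = t$transcript_support_level,
                            stringsAsFactors = FALSE)
  exons <- data.frame(transcript_id = e$transcript_id, gene_id = e$gene_id,
                      exon_number = suppressWarnings(as.integer(e$exon_number)),
                      chrom = e$seqnames, start = e$start, end = e$end,
                      strand = e$strand, stringsAsFactors = FALSE)
  cds <- if (nrow(cc)) data.frame(transcript_id = cc$transcript_id,
                                  chrom = cc$seqnames, start = cc$start,
                                  end = cc$end, strand = cc$strand,
                                  stringsAsFactors = FALSE) else empty_cds()
  new_annotation(genes, transcripts, exons, cds)
}

#' Write a transcript annotation as a GENCODE-dialect GTF
#'
#' Emits gene, transcript, exon and CDS records with `gene_id`,
#' `transcript_id`, `gene_type`, `level` and `transcript_support_level`
#' attributes.
#'
#' @param annotation A `transcript_annotation`.
#' @param path Output GTF path.
#' @export
write_gtf <- function(annotation, path) {
  g <- annotation$genes; t <- annotation$transcripts
  e <- annotation$exons; cc <- annotation$cds
  tsl_of <- t$tsl[match(e$transcript_id, t$transcript_id)]
  gene_of_tx <- t$gene_id
  rows <- rbind(
    data.frame(type = "gene", chrom = g$chrom, start = g$start, end = g$end,
               strand = g$strand, gene_id = g$gene_id,
               transcript_id = NA_character_, gene_type = g$gene_type,
               level = g$level, tsl = NA_character_,
               exon_number = NA_integer_, stringsAsFactors = FALSE),
    data.frame(type = "transcript", chrom = t$chrom, start = t$start,
               end = t$end, strand = t$strand, gene_id = t$gene_id,
               transcript_id = t$transcript_id,
               gene_type = g$gene_type[match(t$gene_id, g$gene_id)],
               level = g$level[match(t$gene_id, g$gene_id)], tsl = t$tsl,
               exon_number = NA_integer_, stringsAsFactors = FALSE),
    data.frame(type = "exon", chrom = e$chrom, start = e$start, end = e$end,
               strand = e$strand, gene_id = e$gene_id,
               transcript_id = e$transcript_id,
               gene_type = g$gene_type[match(e$gene_id, g$gene_id)],
               level = g$level[match(e$gene_id, g$gene_id)], tsl = tsl_of,
               exon_number = e$exon_number, stringsAsFactors = FALSE),
    if (nrow(cc)) data.frame(
      type = "CDS", chrom = cc$chrom, start = cc$start, end = cc$end,
      strand = cc$strand,
      gene_id = t$gene_id[match(cc$transcript_id, t$transcript_id)],
      transcript_id = cc$transcript_id,
      gene_type = "protein_coding",
      level = g$level[match(t$gene_id[match(cc$transcript_id,
                                            t$transcript_id)], g$gene_id)],
      tsl = t$tsl[match(cc$transcript_id, t$transcript_id)],
      exon_number = NA_integer_, stringsAsFactors = FALSE))
  gr <- GenomicRanges::GRanges(rows$chrom,
                               IRanges::IRanges(rows$start, rows$end),
                               strand = rows$strand)
  S4Vectors::mcols(gr) <- S4Vectors::DataFrame(
    source = "clipmap_synth", type = rows$type, gene_id = rows$gene_id,
    transcript_id = rows$transcript_id, gene_type = rows$gene_type,
    level = as.character(rows$level),
    transcript_support_level = rows$tsl,
    exon_number = as.character(rows$exon_number),
    phase = ifelse(rows$type == "CDS", 0L, NA_integer_))
  rtracklayer::export(gr, path, format = "gtf")
  invisible(path)
}

genes_granges <- function(genes) {
  GenomicRanges::GRanges(genes$chrom,
                         IRanges::IRanges(genes$start, genes$end),
                         strand = genes$strand, gene_id = genes$gene_id,
                         gene_type = genes$gene_type)
}

sites_granges <- function(binding_sites) {
  GenomicRanges::GRanges(binding_sites$chrom,
                         IRanges::IRanges(binding_sites$start,
                                          binding_sites$end),
                         strand = binding_sites$strand)
}

#' Assign binding sites to unique genes
#'
#' Strand-matched overlap of binding sites with (optionally protein-coding)
#' filtered genes. With `remove_overlapping_genes` (default), genes whose
#' spans overlap another retained gene on the same strand are removed before
#' assignment. Sites overlapping exactly one gene get that gene; sites
#' overlapping several are `"ambiguous"`, sites overlapping none `"none"` --
#' both are excluded from region analysis.
#'
#' @param binding_sites A `binding_sites` table.
#' @param annotation A `transcript_annotation`.
#' @param protein_coding_only Restrict to protein-coding genes (default
#'   TRUE; set FALSE for gene-biotype distributions).
#' @param remove_overlapping_genes Drop same-strand overlapping genes first.
#' @return `binding_sites` with an added `gene_id` column (gene id,
#'   `"ambiguous"` or `"none"`).
#' @export
assign_unique_gene <- function(binding_sites, annotation,
                               protein_coding_only = TRUE,
                               remove_overlapping_genes = TRUE) {
  genes <- annotation$genes
  if (protein_coding_only)
    genes <- genes[genes$gene_type == "protein_coding", , drop = FALSE]
  if (remove_overlapping_genes && nrow(genes) > 1L) {
    gg <- genes_granges(genes)
    ov <- GenomicRanges::countOverlaps(gg, gg)  # strand-aware; self counts 1
    genes <- genes[ov == 1L, , drop = FALSE]
  }
  gg <- genes_granges(genes)
  hits <- GenomicRanges::findOverlaps(sites_granges(binding_sites), gg)
  nhit <- GenomicRanges::countOverlaps(sites_granges(binding_sites), gg)
  gene_id <- rep("none", nrow(binding_sites))
  gene_id[nhit > 1L] <- "ambiguous"
  one <- which(nhit == 1L)
  first_hit <- S4Vectors::subjectHits(hits)[match(one,
                                                  S4Vectors::queryHits(hits))]
  gene_id[one] <- genes$gene_id[first_hit]
  binding_sites$gene_id <- gene_id
  binding_sites
}

region_rank <- c(intron = 1L, CDS = 2L, UTR3 = 3L, UTR5 = 4L, exon = 5L)

#' Assign uniquely gene-assigned binding sites to transcript regions
#'
#' For each site with a unique gene, every retained transcript of that gene
#' votes with the region it sees the site in (multi-region overlaps within a
#' transcript are resolved by the hierarchy intron > CDS > 3'UTR > 5'UTR);
#' the final label is the majority vote, ties broken by the same hierarchy.
#' Transcripts without CDS records vote `intron` when they overlap the site
#' in an intron and otherwise abstain from coding-region labels (their
#' exonic overlap is only informative for non-coding genes).
#'
#' @param assigned Binding sites with a `gene_id` column from
#'   [assign_unique_gene()].
#' @param annotation A `transcript_annotation`.
#' @return The input with added `region` label (NA for
#'   ambiguous/none/unresolved sites) and per-label vote-count columns
#'   `votes_intron`, `votes_CDS`, `votes_UTR3`, `votes_UTR5`.
#' @export
assign_region <- function(assigned, annotation) {
  reg <- annotation$regions
  rgr <- GenomicRanges::GRanges(reg$chrom,
                                IRanges::IRanges(reg$start, reg$end),
                                strand = reg$strand)
  sgr <- sites_granges(assigned)
  hits <- GenomicRanges::findOverlaps(sgr, rgr)
  qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
  labels <- c("intron", "CDS", "UTR3", "UTR5")
  votes <- matrix(0L, nrow(assigned), 4L,
                  dimnames = list(NULL, labels))
  region <- rep(NA_character_, nrow(assigned))
  real_gene <- !(assigned$gene_id %in% c("ambiguous", "none"))
  for (q in unique(qh)) {
    if (!real_gene[q]) next
    h <- sh[qh == q]
    h <- h[reg$gene_id[h] == assigned$gene_id[q]]
    if (!length(h)) next
    # per overlapping transcript: best label by hierarchy
    per_tx <- tapply(reg$region[h], reg$transcript_id[h], function(rr) {
      rr <- rr[rr %in% labels | rr == "exon"]
      if (all(rr == "exon")) return(NA_character_)  # CDS-absent transcript
      rr <- rr[rr %in% labels]
      rr[which.min(region_rank[rr])]
    })
    per_tx <- per_tx[!is.na(per_tx)]
    if (!length(per_tx)) next
    tab <- table(factor(per_tx, levels = labels))
    votes[q, ] <- as.integer(tab)
    best <- names(tab)[tab == max(tab)]
    region[q] <- best[which.min(region_rank[best])]
  }
  assigned$region <- region
  for (l in labels) assigned[[paste0("votes_", l)]] <- votes[, l]
  assigned
}

#' Length-normalized binding-site density per transcript region
#'
#' Number of assigned sites per region label divided by the summed length of
#' that region type over all transcripts of bound genes (genes carrying at
#' least one assigned site), reported per 1,000 nt.
#'
#' @param assigned Output of [assign_region()].
#' @param annotation A `transcript_annotation`.
#' @return Data.frame with `region`, `n_sites`, `region_nt`,
#'   `sites_per_kb`.
#' @export
region_enrichment <- function(assigned, annotation) {
  labels <- c("intron", "CDS", "UTR3", "UTR5")
  bound_genes <- unique(assigned$gene_id[!is.na(assigned$region)])
  reg <- annotation$regions
  reg <- reg[reg$gene_id %in% bound_genes, , drop = FALSE]
  len <- vapply(labels, function(l) {
    r <- reg[reg$region == l, , drop = FALSE]
    sum(r$end - r$start + 1)
  }, 0)
  n <- vapply(labels, function(l) sum(assigned$region %in% l), 0)
  data.frame(region = labels, n_sites = n, region_nt = len,
             sites_per_kb = ifelse(len > 0, 1000 * n / len, NA_real_),
             stringsAsFactors = FALSE)
}

#' Gene-biotype distribution of binding sites
#'
#' Fraction of uniquely gene-assigned binding sites per gene biotype
#' (unique-gene rule over genes of all biotypes).
#'
#' @param binding_sites A `binding_sites` table.
#' @param annotation A `transcript_annotation`.
#' @return Data.frame with `gene_type`, `n_sites`, `fraction` (summing to 1;
#'   zero rows when no site is assignable).
#' @export
gene_type_distribution <- function(binding_sites, annotation) {
  a <- assign_unique_gene(binding_sites, annotation,
                          protein_coding_only = FALSE,
                          remove_overlapping_genes = FALSE)
  a <- a[!(a$gene_id %in% c("ambiguous", "none")), , drop = FALSE]
  if (nrow(a) == 0L)
    return(data.frame(gene_type = character(), n_sites = integer(),
                      fraction = numeric(), stringsAsFactors = FALSE))
  bt <- annotation$genes$gene_type[match(a$gene_id, annotation$genes$gene_id)]
  tab <- table(bt)
  data.frame(gene_type = names(tab), n_sites = as.integer(tab),
             fraction = as.numeric(tab) / sum(tab), stringsAsFactors = FALSE)
}
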