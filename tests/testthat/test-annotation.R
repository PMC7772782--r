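# Hand-built GTFs let the filters and voting rules be checked exactly.

write_test_gtf <- function(lines) {
  f <- tempfile(fileext = ".gtf")
  writeLines(lines, f)
  f
}

gtf_line <- function(type, start, end, strand, gene, tx = NULL,
                     gene_type = "protein_coding", level = 1, tsl = 1,
                     exon = NULL) {
  attrs <- sprintf('gene_id "%s"; gene_type "%s"; level %s;',
                   gene, gene_type, level)
  if (!is.null(tx))
    attrs <- paste(attrs,
                   sprintf('transcript_id "%s"; transcript_support_level "%s";',
                           tx, tsl))
  if (!is.null(exon)) attrs <- paste(attrs, sprintf('exon_number %d;', exon))
  paste("chrT", "test", type, start, end, ".", strand, ".", attrs,
        sep = "\t")
}

test_that("annotation support filters are applied on load", {
  f <- write_test_gtf(c(
    gtf_line(type = "gene", 1, 1000, "+", gene = "G1", level = 2),
    gtf_line(type = "transcript", 1, 1000, "+", "G1", "T1", tsl = 3),
    gtf_line(type = "exon", 1, 400, "+", "G1", "T1", exon = 1),
    gtf_line(type = "exon", 601, 1000, "+", "G1", "T1", exon = 2),
    gtf_line(type = "transcript", 1, 1000, "+", "G1", "T2", tsl = 4),
    gtf_line(type = "exon", 1, 1000, "+", "G1", "T2", exon = 1),
    gtf_line(type = "transcript", 1, 1000, "+", "G1", "T3", tsl = "NA"),
    gtf_line(type = "exon", 1, 1000, "+", "G1", "T3", exon = 1),
    gtf_line(type = "gene", 2000, 3000, "+", gene = "G2", level = 3),
    gtf_line(type = "transcript", 2000, 3000, "+", "G2", "T4", tsl = 1),
    gtf_line(type = "exon", 2000, 3000, "+", "G2", "T4", exon = 1)))
  ann <- load_annotation(f)
  expect_identical(ann$genes$gene_id, "G1")       # level 2 kept, level 3 out
  expect_identical(ann$transcripts$transcript_id, "T1")  # TSL 4 and NA out
})

test_that("derived introns equal the exon complement (interval oracle)", {
  set.seed(12)
  for (rep_i in 1:20) {
    n_ex <- sample(2:6, 1)
    len <- sample(50:150, n_ex, replace = TRUE)
    gaps <- sample(60:200, n_ex - 1, replace = TRUE)
    start <- 1000 + cumsum(c(0, len[-n_ex] + gaps))
    end <- start + len - 1
    strand <- sample(c("+", "-"), 1)
    lines <- c(
      gtf_line(type = "gene", min(start), max(end), strand, "G1"),
      gtf_line(type = "transcript", min(start), max(end), strand, "G1", "T1"),
      vapply(seq_len(n_ex), function(j)
        gtf_line(type = "exon", start[j], end[j], strand, "G1", "T1",
                 exon = j), ""))
    ann <- load_annotation(write_test_gtf(lines))
    introns <- ann$regions[ann$regions$region == "intron", ]
    ex_ir <- IRanges::IRanges(start, end)
    want <- IRanges::setdiff(range(ex_ir), ex_ir)
    expect_identical(introns$start, IRanges::start(want))
    expect_identical(introns$end, IRanges::end(want))
  }
})

test_that("CDS and UTR derivation is strand-aware", {
  lines <- c(
    gtf_line(type = "gene", 100, 1000, "-", "G1"),
    gtf_line(type = "transcript", 100, 1000, "-", "G1", "T1"),
    gtf_line(type = "exon", 100, 300, "-", "G1", "T1", exon = 2),
    gtf_line(type = "exon", 700, 1000, "-", "G1", "T1", exon = 1),
    gtf_line(type = "CDS", 200, 300, "-", "G1", "T1"),
    gtf_line(type = "CDS", 700, 900, "-", "G1", "T1"))
  ann <- load_annotation(write_test_gtf(lines))
  reg <- ann$regions
  # minus strand: genomic-left of the CDS span is the 3' UTR
  expect_identical(reg$region[reg$start == 100 & reg$end == 199], "UTR3")
  expect_identical(reg$region[reg$start == 901 & reg$end == 1000], "UTR5")
  expect_setequal(reg$start[reg$region == "CDS"], c(200L, 700L))
  expect_identical(reg$region[reg$start == 301], "intron")
})

mk_sites <- function(start, strand = "+", chrom = "chrT") {
  start <- as.integer(start)
  data.frame(chrom = rep(chrom, length(start)), start = start,
             end = start + 8L,
             strand = rep(strand, length(start)), center = start + 4L,
             site_id = sprintf("BS%03d", seq_along(start)),
             stringsAsFactors = FALSE)
}

test_that("unique-gene assignment flags ambiguous and unassigned sites", {
  lines <- c(
    gtf_line(type = "gene", 100, 1000, "+", "G1"),
    gtf_line(type = "transcript", 100, 1000, "+", "G1", "T1"),
    gtf_line(type = "exon", 100, 1000, "+", "G1", "T1", exon = 1),
    gtf_line(type = "gene", 900, 1500, "+", "G2"),
    gtf_line(type = "transcript", 900, 1500, "+", "G2", "T2"),
    gtf_line(type = "exon", 900, 1500, "+", "G2", "T2", exon = 1),
    gtf_line(type = "gene", 3000, 3500, "+", "G3"),
    gtf_line(type = "transcript", 3000, 3500, "+", "G3", "T3"),
    gtf_line(type = "exon", 3000, 3500, "+", "G3", "T3", exon = 1),
    gtf_line(type = "gene", 3000, 3500, "-", "G4", gene_type = "lncRNA"),
    gtf_line(type = "transcript", 3000, 3500, "-", "G4", "T4",
             gene_type = "lncRNA"),
    gtf_line(type = "exon", 3000, 3500, "-", "G4", "T4",
             gene_type = "lncRNA", exon = 1))
  ann <- load_annotation(write_test_gtf(lines))
  sites <- mk_sites(c(200, 950, 3100, 5000))
  # G1/G2 overlap each other: removed by the overlapping-annotations filter
  a <- assign_unique_gene(sites, ann)
  expect_identical(a$gene_id, c("none", "none", "G3", "none"))
  # without that filter the spanning site is ambiguous
  a2 <- assign_unique_gene(sites, ann, remove_overlapping_genes = FALSE)
  expect_identical(a2$gene_id, c("G1", "ambiguous", "G3", "none"))
  # strandedness: a minus-strand site at 3100 goes to the lncRNA gene only
  m <- assign_unique_gene(mk_sites(3100, strand = "-"), ann,
                          protein_coding_only = FALSE)
  expect_identical(m$gene_id, "G4")
})

test_that("region votes use majority then the intron>CDS>UTR3>UTR5 hierarchy", {
  # three transcripts of one gene disagreeing about one locus
  lines <- c(
    gtf_line(type = "gene", 100, 2000, "+", "G1"),
    # T1, T2: locus 950..1050 is CDS-exonic
    unlist(lapply(c("T1", "T2"), function(tx) c(
      gtf_line(type = "transcript", 100, 2000, "+", "G1", tx),
      gtf_line(type = "exon", 100, 200, "+", "G1", tx, exon = 1),
      gtf_line(type = "exon", 900, 1100, "+", "G1", tx, exon = 2),
      gtf_line(type = "exon", 1900, 2000, "+", "G1", tx, exon = 3),
      gtf_line(type = "CDS", 150, 200, "+", "G1", tx),
      gtf_line(type = "CDS", 900, 1100, "+", "G1", tx),
      gtf_line(type = "CDS", 1900, 1950, "+", "G1", tx)))),
    # T3: intron-retaining structure, locus is intronic
    gtf_line(type = "transcript", 100, 2000, "+", "G1", "T3"),
    gtf_line(type = "exon", 100, 200, "+", "G1", "T3", exon = 1),
    gtf_line(type = "exon", 1900, 2000, "+", "G1", "T3", exon = 2),
    gtf_line(type = "CDS", 150, 200, "+", "G1", "T3"),
    gtf_line(type = "CDS", 1900, 1950, "+", "G1", "T3"))
  ann <- load_annotation(write_test_gtf(lines))
  a <- assign_region(assign_unique_gene(mk_sites(1000), ann), ann)
  expect_identical(a$region, "CDS")       # majority 2 CDS vs 1 intron
  expect_identical(a$votes_CDS, 2L)
  expect_identical(a$votes_intron, 1L)
})

test_that("vote ties break along the hierarchy", {
  # one CDS transcript vs one intron transcript -> intron
  lines <- c(
    gtf_line(type = "gene", 100, 2000, "+", "G1"),
    gtf_line(type = "transcript", 100, 2000, "+", "G1", "T1"),
    gtf_line(type = "exon", 100, 200, "+", "G1", "T1", exon = 1),
    gtf_line(type = "exon", 900, 1100, "+", "G1", "T1", exon = 2),
    gtf_line(type = "exon", 1900, 2000, "+", "G1", "T1", exon = 3),
    gtf_line(type = "CDS", 150, 1950, "+", "G1", "T1"),
    gtf_line(type = "transcript", 100, 2000, "+", "G1", "T2"),
    gtf_line(type = "exon", 100, 200, "+", "G1", "T2", exon = 1),
    gtf_line(type = "exon", 1900, 2000, "+", "G1", "T2", exon = 2),
    gtf_line(type = "CDS", 150, 1950, "+", "G1", "T2"))
  ann <- load_annotation(write_test_gtf(lines))
  a <- assign_region(assign_unique_gene(mk_sites(1000), ann), ann)
  expect_identical(a$region, "intron")
  # UTR3 vs UTR5 tie -> UTR3: two single-exon transcripts with opposed CDS
  lines2 <- c(
    gtf_line(type = "gene", 100, 1000, "+", "G1"),
    gtf_line(type = "transcript", 100, 1000, "+", "G1", "T1"),
    gtf_line(type = "exon", 100, 1000, "+", "G1", "T1", exon = 1),
    gtf_line(type = "CDS", 100, 400, "+", "G1", "T1"),   # site in 3' UTR
    gtf_line(type = "transcript", 100, 1000, "+", "G1", "T2"),
    gtf_line(type = "exon", 100, 1000, "+", "G1", "T2", exon = 1),
    gtf_line(type = "CDS", 700, 1000, "+", "G1", "T2"))  # site in 5' UTR
  ann2 <- load_annotation(write_test_gtf(lines2))
  a2 <- assign_region(assign_unique_gene(mk_sites(500), ann2), ann2)
  expect_identical(a2$region, "UTR3")
})

test_that("region densities are per-kb and calibrated under uniformity", {
  # arithmetic: 10 sites in 1000 nt of CDS -> 10 per kb
  lines <- c(
    gtf_line(type = "gene", 1, 5000, "+", "G1"),
    gtf_line(type = "transcript", 1, 5000, "+", "G1", "T1"),
    gtf_line(type = "exon", 1, 5000, "+", "G1", "T1", exon = 1),
    gtf_line(type = "CDS", 2001, 3000, "+", "G1", "T1"))
  ann <- load_annotation(write_test_gtf(lines))
  sites <- mk_sites(seq(2100, 2900, length.out = 10))
  a <- assign_region(assign_unique_gene(sites, ann), ann)
  d <- region_enrichment(a, ann)
  expect_identical(d$sites_per_kb[d$region == "CDS"], 10)
  expect_identical(d$n_sites[d$region == "UTR5"], 0)
  # uniform placement in the synthetic study: per-region site counts match
  # the length-proportional expectation within Monte-Carlo error
  st <- default_study()
  ann_s <- st$annotation
  good_genes <- ann_s$genes$gene_id[ann_s$genes$gene_type ==
                                      "protein_coding" &
                                      ann_s$genes$level <= 2 &
                                      ann_s$genes$tsl %in% c("1", "2", "3")]
  reg <- ann_s$regions[ann_s$regions$gene_id %in% good_genes, ]
  set.seed(8)
  n_u <- 1000L
  pick <- reg[sample(nrow(reg), n_u, replace = TRUE,
                     prob = reg$end - reg$start + 1), ]
  pos <- pick$start + floor(stats::runif(n_u) * (pick$end - pick$start + 1))
  usites <- data.frame(chrom = pick$chrom, start = as.integer(pos),
                       end = as.integer(pos), strand = pick$strand,
                       site_id = sprintf("U%04d", 1:n_u),
                       stringsAsFactors = FALSE)
  au <- assign_region(assign_unique_gene(usites, ann_s), ann_s)
  du <- region_enrichment(au, ann_s)
  N <- sum(du$n_sites)
  p <- du$region_nt / sum(du$region_nt)
  for (r in seq_len(nrow(du))) {
    se <- sqrt(N * p[r] * (1 - p[r]))
    expect_lt(abs(du$n_sites[r] - N * p[r]), 4 * se + 2)
  }
})

test_that("gene-biotype distribution recovers a planted 80/20 split", {
  lines <- unlist(lapply(1:10, function(i) {
    s <- 1000 * i
    gt <- if (i <= 8) "protein_coding" else "lncRNA"
    c(gtf_line(type = "gene", s, s + 500, "+", paste0("G", i), gene_type = gt),
      gtf_line(type = "transcript", s, s + 500, "+", paste0("G", i),
               paste0("T", i), gene_type = gt),
      gtf_line(type = "exon", s, s + 500, "+", paste0("G", i), paste0("T", i),
               gene_type = gt, exon = 1))
  }))
  ann <- load_annotation(write_test_gtf(lines))
  sites <- mk_sites(1000 * (1:10) + 100)
  gd <- gene_type_distribution(sites, ann)
  expect_identical(gd$fraction[gd$gene_type == "protein_coding"], 0.8)
  expect_identical(gd$fraction[gd$gene_type == "lncRNA"], 0.2)
  expect_identical(sum(gd$fraction), 1)
  # empty site set: empty distribution, no division by zero
  empty <- gene_type_distribution(mk_sites(integer(0)), ann)
  expect_identical(nrow(empty), 0L)
})

test_that("assignment is deterministic and unique per site", {
  st <- default_study()
  bs <- suppressWarnings(call_binding_sites(
    st$tracks$sites, st$tracks$merged, st$tracks$replicates,
    chrom_lengths = chrom_lengths(st$genome)))
  a1 <- assign_region(assign_unique_gene(bs, st$annotation), st$annotation)
  a2 <- assign_region(assign_unique_gene(bs, st$annotation), st$annotation)
  expect_identical(a1, a2)
  ok <- !is.na(a1$region)
  expect_true(all(a1$region[ok] %in% c("intron", "CDS", "UTR3", "UTR5")))
  votes <- a1$votes_intron + a1$votes_CDS + a1$votes_UTR3 + a1$votes_UTR5
  expect_true(all(votes[ok] >= 1))
})
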