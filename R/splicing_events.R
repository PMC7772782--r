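#' Read and write cassette-exon tables in the rMATS SE dialect
#'
#' The on-disk format follows rMATS skipped-exon (SE) output: 0-based exon
#' start coordinates, comma-joined per-replicate inclusion/skipping junction
#' counts (`IJC_SAMPLE_1` etc.) and inclusion levels (`IncLevel1`/`IncLevel2`),
#' with `SAMPLE_1` = control and `SAMPLE_2` = knockdown by default.
#' Internally events use 1-based closed coordinates, `psi_ctl`/`psi_kd`
#' replicate strings, and `dpsi` = mean KD PSI minus mean control PSI, so a
#' negative `dpsi` means less inclusion (more skipping) after knockdown.
#'
#' Rows violating the schema (PSI outside `[0, 1]`, FDR outside `[0, 1]`,
#' non-positive exon intervals) are rejected with a warning naming the row
#' numbers.
#'
#' @param path TSV path.
#' @param control_sample Which rMATS sample block is the control, 1 or 2.
#' @return A `ce_events` data.frame.
#' @export
read_ce_table <- function(path, control_sample = 1) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "")
  if (nrow(df) == 0L) return(empty_ce_events())
  ctl <- if (control_sample == 1) "1" else "2"
  kd <- if (control_sample == 1) "2" else "1"
  psi_ctl <- df[[paste0("IncLevel", ctl)]]
  psi_kd <- df[[paste0("IncLevel", kd)]]
  out <- data.frame(
    event_id = df$ID, gene_id = df$GeneID, chrom = df$chr, strand = df$strand,
    up_start = df$upstreamES + 1L, up_end = df$upstreamEE,
    alt_start = df$exonStart_0base + 1L, alt_end = df$exonEnd,
    down_start = df$downstreamES + 1L, down_end = df$downstreamEE,
    psi_ctl = psi_ctl, psi_kd = psi_kd,
    ijc_ctl = df[[paste0("IJC_SAMPLE_", ctl)]],
    sjc_ctl = df[[paste0("SJC_SAMPLE_", ctl)]],
    ijc_kd = df[[paste0("IJC_SAMPLE_", kd)]],
    sjc_kd = df[[paste0("SJC_SAMPLE_", kd)]],
    pvalue = df$PValue, fdr = df$FDR, stringsAsFactors = FALSE)
  pc <- split_reps(out$psi_ctl)
  pk <- split_reps(out$psi_kd)
  out$psi_ctl_mean <- rowMeans(pc)
  out$psi_kd_mean <- rowMeans(pk)
  out$dpsi <- out$psi_kd_mean - out$psi_ctl_mean

  bad_psi <- apply(cbind(pc, pk), 1L, function(v)
    any(is.na(v)) || any(v < 0) || any(v > 1))
  bad_fdr <- is.na(out$fdr) | out$fdr < 0 | out$fdr > 1
  bad_coord <- out$up_start > out$up_end | out$alt_start > out$alt_end |
    out$down_start > out$down_end
  bad <- which(bad_psi | bad_fdr | bad_coord)
  if (length(bad)) {
    warning(sprintf("rejecting %d malformed row(s): %s", length(bad),
                    paste(bad, collapse = ", ")))
    out <- out[-bad, , drop = FALSE]
  }
  rownames(out) <- NULL
  out <- out[, names(empty_ce_events())]
  class(out) <- c("ce_events", "data.frame")
  out
}

#' @rdname read_ce_table
#' @param events A `ce_events` data.frame.
#' @export
write_ce_table <- function(events, path) {
  pc <- if (nrow(events)) rowMeans(split_reps(events$psi_ctl)) else numeric()
  pk <- if (nrow(events)) rowMeans(split_reps(events$psi_kd)) else numeric()
  df <- data.frame(
    ID = events$event_id, GeneID = events$gene_id, geneSymbol = events$gene_id,
    chr = events$chrom, strand = events$strand,
    exonStart_0base = events$alt_start - 1L, exonEnd = events$alt_end,
    upstreamES = events$up_start - 1L, upstreamEE = events$up_end,
    downstreamES = events$down_start - 1L, downstreamEE = events$down_end,
    IJC_SAMPLE_1 = events$ijc_ctl, SJC_SAMPLE_1 = events$sjc_ctl,
    IJC_SAMPLE_2 = events$ijc_kd, SJC_SAMPLE_2 = events$sjc_kd,
    IncFormLen = 198L, SkipFormLen = 99L,
    PValue = events$pvalue, FDR = events$fdr,
    IncLevel1 = events$psi_ctl, IncLevel2 = events$psi_kd,
    IncLevelDifference = round(pc - pk, 4), stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Junction-read support per event
#'
#' Mean over all replicate measurements (both conditions) of the per-replicate
#' sum of inclusion plus skipping junction reads. With `log_before_mean` the
#' per-replicate sums are log2-transformed before averaging (the alternative
#' reading of "log2-transformed sum, mean between replicates").
#'
#' @param events `ce_events`.
#' @param log_before_mean Logical.
#' @return If `log_before_mean`, the mean log2 support; otherwise the plain
#'   mean support (take `log2()` of it for filtering).
#' @export
junction_support <- function(events, log_before_mean = FALSE) {
  if (nrow(events) == 0L) return(numeric(0))
  jc <- cbind(split_reps(events$ijc_ctl) + split_reps(events$sjc_ctl),
              split_reps(events$ijc_kd) + split_reps(events$sjc_kd))
  if (log_before_mean) rowMeans(log2(jc)) else rowMeans(jc)
}

#' Partition cassette exons into regulated and unchanged sets
#'
#' An event is significant when `FDR < fdr`, `|dPSI| > min_abs_dpsi`, and the
#' log2 mean junction-read support exceeds `min_log2_jc` (all thresholds
#' strict). Significant events route to the `down` set (dPSI < 0: less
#' inclusion after knockdown) or `up` set; everything else forms the
#' `unchanged` pool used for background matching.
#'
#' @param events `ce_events`.
#' @param fdr,min_abs_dpsi,min_log2_jc Thresholds.
#' @param log_before_mean See [junction_support()].
#' @return A `regulated_sets` list with `down`, `up`, `unchanged` (disjoint
#'   `ce_events` whose union is the input).
#' @export
filter_significant_events <- function(events, fdr = 0.05,
                                      min_abs_dpsi = 0.05, min_log2_jc = 5,
                                      log_before_mean = FALSE) {
  jc <- junction_support(events, log_before_mean = log_before_mean)
  log_jc <- if (log_before_mean) jc else log2(jc)
  sig <- events$fdr < fdr & abs(events$dpsi) > min_abs_dpsi &
    log_jc > min_log2_jc
  sig[is.na(sig)] <- FALSE
  structure(list(down = events[sig & events$dpsi < 0, , drop = FALSE],
                 up = events[sig & events$dpsi > 0, , drop = FALSE],
                 unchanged = events[!sig, , drop = FALSE]),
            class = "regulated_sets")
}

#' @export
print.regulated_sets <- function(x, ...) {
  cat(sprintf("regulated cassette exons: %d down, %d up, %d unchanged\n",
              nrow(x$down), nrow(x$up), nrow(x$unchanged)))
  invisible(x)
}

#' Binding sites within the alternatively spliced region
#'
#' The alternatively spliced region of an event spans, in transcript
#' orientation, from `flank` nt upstream of the 5' splice site of the
#' upstream constitutive exon to `flank` nt downstream of the 3' splice site
#' of the downstream constitutive exon. Each event is annotated with the
#' number of strand-matched binding sites inside that window and the
#' strongest site strength among them.
#'
#' @param events `ce_events`.
#' @param binding_sites Binding-site table from [define_binding_sites()] /
#'   [reproducibility_filter()].
#' @param flank Window extension in nt (default 100).
#' @return `events` with columns `n_sites_as_region`, `max_site_strength`
#'   (NA when no site overlaps) and a list-ish `site_ids` string column.
#' @export
as_region_overlap <- function(events, binding_sites, flank = 100) {
  if (nrow(events) == 0L) {
    events$n_sites_as_region <- integer(0)
    events$max_site_strength <- numeric(0)
    events$site_ids <- character(0)
    return(events)
  }
  plus <- events$strand == "+"
  # 5'ss (donor) of the upstream exon is its transcript-orientation last
  # base; 3'ss (acceptor) of the downstream exon its first. On the minus
  # strand these sit at the genomic start/end respectively.
  win_start <- ifelse(plus, events$up_end - flank, events$down_end - flank)
  win_end <- ifelse(plus, events$down_start + flank, events$up_start + flank)
  win <- GenomicRanges::GRanges(events$chrom,
                                IRanges::IRanges(pmax(1L, win_start), win_end),
                                strand = events$strand)
  bs <- GenomicRanges::GRanges(binding_sites$chrom,
                               IRanges::IRanges(binding_sites$start,
                                                binding_sites$end),
                               strand = binding_sites$strand)
  hits <- GenomicRanges::findOverlaps(win, bs)
  n <- integer(nrow(events))
  mx <- rep(NA_real_, nrow(events))
  ids <- character(nrow(events))
  if (length(hits)) {
    qh <- S4Vectors::queryHits(hits); sh <- S4Vectors::subjectHits(hits)
    for (q in unique(qh)) {
      s <- sh[qh == q]
      n[q] <- length(s)
      mx[q] <- max(binding_sites$strength[s])
      ids[q] <- paste(binding_sites$site_id[s], collapse = ",")
    }
  }
  events$n_sites_as_region <- n
  events$max_site_strength <- mx
  events$site_ids <- ids
  events
}

#' Percent inclusion from amplicon molarities
#'
#' RT-PCR readout: the molar amount of the inclusion (bigger) amplicon over
#' the total, as a percentage.
#'
#' @param molarity_long,molarity_short Non-negative molarities of the
#'   inclusion and skipping amplicons; not both zero.
#' @return Percentage in `[0, 100]`.
#' @export
percent_inclusion <- function(molarity_long, molarity_short) {
  if (any(molarity_long < 0) || any(molarity_short < 0))
    stopf("molarities must be >= 0")
  if (any(molarity_long + molarity_short == 0))
    stopf("molarities must not both be zero")
  100 * molarity_long / (molarity_long + molarity_short)
}

#' Intersect regulated sets with a gene list
#'
#' @param sets A `regulated_sets` object.
#' @param gene_list Character vector of gene ids (e.g. disease-susceptibility
#'   genes).
#' @return A list per set with the subset of events, plus `n_genes` /
#'   `n_events` counts.
#' @export
intersect_gene_list <- function(sets, gene_list) {
  lapply(sets[c("down", "up", "unchanged")], function(ev) {
    sub <- ev[ev$gene_id %in% gene_list, , drop = FALSE]
    list(events = sub, n_genes = length(unique(sub$gene_id)),
         n_events = nrow(sub))
  })
}
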