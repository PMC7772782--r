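#' Simulate a paired control/knockdown cassette-exon PSI table
#'
#' Produces one cassette-exon event per gene, with the gene's designated
#' alternative exon flanked by its constitutive neighbours. Per-replicate PSI
#' values (paired control/KD design) are beta-distributed around the
#' catalog's per-gene means with a shared per-pair offset inducing the paired
#' structure. The significance columns mimic an rMATS table: a paired t-test
#' p-value per event and Benjamini-Hochberg FDR across all events. Junction
#' reads are Poisson around `read_depth`, with a small fraction of events at
#' low depth so the junction-read filter has something to reject.
#'
#' @param annotation `transcript_annotation` from the generator.
#' @param catalog Catalog from [plant_motifs()] (supplies per-gene class,
#'   control-PSI mean and dPSI).
#' @param config A [synth_config()].
#' @return A `ce_events` data.frame (see [read_ce_table()] for the schema).
#' @export
simulate_ce_table <- function(annotation, catalog, config) {
  validate_synth_config(config)
  genes <- annotation$genes
  n <- nrow(genes)
  if (n == 0L) return(empty_ce_events())
  ex_by_gene <- split(annotation$exons, annotation$exons$gene_id)
  cat_genes <- catalog$genes
  nrep <- config$n_psi_replicates
  conc <- config$psi_concentration

  rows <- vector("list", n)
  pvals <- numeric(n)
  for (i in seq_len(n)) {
    g <- genes[i, ]
    ci <- match(g$gene_id, cat_genes$gene_id)
    m_ctl <- cat_genes$psi_ctl_mean[ci]
    m_kd <- min(max(m_ctl + cat_genes$dpsi[ci], 0.005), 0.995)
    ex <- ex_by_gene[[g$gene_id]]
    ord <- if (g$strand == "+") order(ex$start) else order(-ex$start)
    ex <- ex[ord, , drop = FALSE]
    a <- g$alt_exon_number
    with_seed(substream_seed(config$seed, i, "psi"), {
      delta <- stats::rnorm(nrep, 0, config$pair_sd)
      mc <- pmin(pmax(m_ctl + delta, 0.005), 0.995)
      mk <- pmin(pmax(m_kd + delta, 0.005), 0.995)
      psi_ctl <- stats::rbeta(nrep, mc * conc, (1 - mc) * conc)
      psi_kd <- stats::rbeta(nrep, mk * conc, (1 - mk) * conc)
      lambda <- if (stats::runif(1) < config$low_depth_fraction) 12
                else config$read_depth
      depth_ctl <- stats::rpois(nrep, lambda)
      depth_kd <- stats::rpois(nrep, lambda)
      ijc_ctl <- stats::rbinom(nrep, depth_ctl, psi_ctl)
      ijc_kd <- stats::rbinom(nrep, depth_kd, psi_kd)
      p <- tryCatch(stats::t.test(psi_kd, psi_ctl, paired = TRUE)$p.value,
                    error = function(e) 1)
      pvals[i] <- if (is.na(p)) 1 else p
      rows[[i]] <- data.frame(
        event_id = i, gene_id = g$gene_id, chrom = g$chrom, strand = g$strand,
        up_start = ex$start[a - 1L], up_end = ex$end[a - 1L],
        alt_start = ex$start[a], alt_end = ex$end[a],
        down_start = ex$start[a + 1L], down_end = ex$end[a + 1L],
        psi_ctl = paste(round(psi_ctl, 4), collapse = ","),
        psi_kd = paste(round(psi_kd, 4), collapse = ","),
        ijc_ctl = paste(ijc_ctl, collapse = ","),
        sjc_ctl = paste(depth_ctl - ijc_ctl, collapse = ","),
        ijc_kd = paste(ijc_kd, collapse = ","),
        sjc_kd = paste(depth_kd - ijc_kd, collapse = ","),
        psi_ctl_mean = mean(psi_ctl), psi_kd_mean = mean(psi_kd),
        dpsi = mean(psi_kd) - mean(psi_ctl),
        pvalue = pvals[i], stringsAsFactors = FALSE)
    })
  }
  out <- do.call(rbind, rows)
  out$fdr <- stats::p.adjust(out$pvalue, method = "BH")
  class(out) <- c("ce_events", "data.frame")
  out
}

empty_ce_events <- function() {
  out <- data.frame(event_id = integer(), gene_id = character(),
                    chrom = character(), strand = character(),
                    up_start = integer(), up_end = integer(),
                    alt_start = integer(), alt_end = integer(),
                    down_start = integer(), down_end = integer(),
                    psi_ctl = character(), psi_kd = character(),
                    ijc_ctl = character(), sjc_ctl = character(),
                    ijc_kd = character(), sjc_kd = character(),
                    psi_ctl_mean = numeric(), psi_kd_mean = numeric(),
                    dpsi = numeric(), pvalue = numeric(), fdr = numeric(),
                    stringsAsFactors = FALSE)
  class(out) <- c("ce_events", "data.frame")
  out
}

# Parse a comma-joined replicate column into a numeric matrix (events x reps).
split_reps <- function(x) {
  vals <- strsplit(x, ",", fixed = TRUE)
  n <- lengths(vals)
  if (length(unique(n)) > 1L) stopf("ragged replicate column")
  matrix(suppressWarnings(as.numeric(unlist(vals))), nrow = length(x),
         byrow = TRUE)
}
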