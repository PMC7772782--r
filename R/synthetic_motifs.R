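#' Plant GAA-repeat motif runs and assign cassette-exon regulation
#'
#' Selects regulated genes, decides per-gene control-PSI means and knockdown
#' dPSI effects, and writes runs of consecutive GAA triplets into the genome:
#' in the alternative-exon body for down-regulated events, in a flanking
#' constitutive exon for up-regulated events, and at a configurable rate in
#' random exons/introns of unregulated genes (neutral sites). On the minus
#' strand the reverse complement (TTC repeats) is written to the reference so
#' the transcribed sequence reads GAA. One non-extending guard base is placed
#' on either side of each run so the planted interval contains exactly the
#' requested number of consecutive triplets.
#'
#' @param genome `DNAStringSet` from [generate_genome_and_annotation()].
#' @param annotation Matching `transcript_annotation`.
#' @param config A [synth_config()].
#' @param seed Seed for the planting stream (defaults to `config$seed`).
#' @return A list with `genome` (edited copy) and `catalog`, itself a list of
#'   `genes` (per-gene regulation class, control-PSI mean, planted dPSI) and
#'   `sites` (planted intervals with `n_triplets` and placement class in
#'   `exon_body_down` / `flanking_exon_up` / `neutral`).
#' @export
plant_motifs <- function(genome, annotation, config, seed = config$seed) {
  validate_synth_config(config)
  genes <- annotation$genes
  n <- nrow(genes)
  seqs <- as.character(genome)
  with_seed(substream_seed(seed, 1L, "plant"), {
    class <- rep("none", n)
    eligible <- which(genes$gene_type == "protein_coding" &
                        genes$level <= 2L &
                        suppressWarnings(as.integer(genes$tsl)) <= 3L)
    eligible <- eligible[!is.na(eligible)]
    n_down <- min(round(config$ce_fraction_down * n), length(eligible))
    picked <- sample(eligible, n_down)
    class[picked] <- "down"
    rest <- setdiff(eligible, picked)
    n_up <- min(round(config$ce_fraction_up * n), length(rest))
    up_picked <- sample(rest, n_up)
    class[up_picked] <- "up"
    neutral <- which(class == "none" &
                       stats::runif(n) < config$neutral_site_rate)
    class[neutral] <- "neutral_site"

    psi <- stats::runif(n, 0.05, 0.95)
    psi[class == "down"] <- stats::runif(sum(class == "down"), 0.40, 0.90)
    psi[class == "up"] <- stats::runif(sum(class == "up"), 0.10, 0.60)
    dpsi <- numeric(n)
    if (config$dpsi_effect > 0) {
      d <- class == "down"; u <- class == "up"
      dpsi[d] <- -pmin(config$dpsi_effect * stats::runif(sum(d), 1, 1.4),
                       psi[d] - 0.02)
      dpsi[u] <- pmin(config$dpsi_effect * stats::runif(sum(u), 1, 1.4),
                      0.98 - psi[u])
    }

    ex_by_gene <- split(annotation$exons, annotation$exons$gene_id)
    reg_by_tx <- split(annotation$regions, annotation$regions$transcript_id)
    sites <- list()
    for (i in seq_len(n)) {
      if (class[i] == "none") next
      g <- genes[i, ]
      ex <- ex_by_gene[[g$gene_id]]
      # transcript-orientation exon index -> genomic exon row
      ord <- if (g$strand == "+") order(ex$start) else order(-ex$start)
      ex <- ex[ord, , drop = FALSE]
      target <- switch(class[i],
        down = ex[g$alt_exon_number, ],
        up = ex[g$alt_exon_number + sample(c(-1L, 1L), 1L), ],
        neutral_site = {
          rg <- reg_by_tx[[g$transcript_id]]
          if (stats::runif(1) < 0.3 && any(rg$region == "intron")) {
            rg <- rg[rg$region == "intron", ]
            rg[sample(nrow(rg), 1L), ]
          } else ex[sample(nrow(ex), 1L), ]
        })
      ntrip <- sample_range(config$motif_repeat_range, 1L)
      run_len <- 3L * ntrip
      avail <- target$end - target$start + 1L - 4L  # 2-nt margin each side
      while (run_len > avail && ntrip > 1L) {
        ntrip <- ntrip - 1L; run_len <- run_len - 3L
      }
      if (run_len > avail) next
      rs <- target$start + 1L +
        sample.int(target$end - target$start - 1L - run_len - 1L, 1L)
      re <- rs + run_len - 1L
      if (g$strand == "+") {
        seqs[g$chrom] <- `substr<-`(seqs[g$chrom], rs - 1L, re + 1L,
                                    paste0("T", strrep("GAA", ntrip), "T"))
      } else {
        seqs[g$chrom] <- `substr<-`(seqs[g$chrom], rs - 1L, re + 1L,
                                    paste0("A", strrep("TTC", ntrip), "A"))
      }
      sites[[length(sites) + 1L]] <- data.frame(
        gene_id = g$gene_id, chrom = g$chrom,
        start = rs - 1L, end = re + 1L, run_start = rs, run_end = re,
        strand = g$strand, n_triplets = ntrip,
        class = switch(class[i], down = "exon_body_down",
                       up = "flanking_exon_up", neutral_site = "neutral"),
        stringsAsFactors = FALSE)
    }
    catalog <- list(
      genes = data.frame(gene_id = genes$gene_id, class = class,
                         psi_ctl_mean = psi, dpsi = dpsi,
                         stringsAsFactors = FALSE),
      sites = if (length(sites)) do.call(rbind, sites) else NULL)
    list(genome = Biostrings::DNAStringSet(seqs), catalog = catalog)
  })
}
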