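#' Simulate replicate crosslink tracks and surrogate significant sites
#'
#' Draws per-nucleotide crosslink-event counts over every gene from a
#' negative-binomial model (`mu = background_rate`, `size = dispersion`),
#' with three multiplicative signals layered on top:
#'
#' * planted motif runs are enriched `enrichment_factor`-fold, ramped so the
#'   rate peaks at the 3' end of the run (the protein positions towards the
#'   end of motif-enriched stretches), and scaled with the number of planted
#'   triplets so stronger motifs yield higher scores;
#' * regulated events carry `region_enrichment`-fold binding over the
#'   alternative-exon body (down-regulated) or the flanking constitutive
#'   exons (up-regulated);
#' * the alternative exon's rate scales with its control inclusion level,
#'   emulating the abundance bias that motivates PSI-matched backgrounds.
#'
#' Significant sites come from a surrogate caller, a deliberately simple
#' stand-in for an HMM peak caller used only on synthetic data: a position is
#' significant when its merged count exceeds the per-gene
#' `background_quantile` count quantile, and its score is the merged count.
#'
#' @param annotation `transcript_annotation` from the generator.
#' @param catalog Planted-site catalog from [plant_motifs()].
#' @param config A [synth_config()].
#' @return List with `replicates` (list of `crosslink_track`), `merged`
#'   (their positionwise sum) and `sites` (a `sig_sites` table).
#' @export
simulate_crosslink_data <- function(annotation, catalog, config) {
  validate_synth_config(config)
  genes <- annotation$genes
  nrep <- config$n_replicates
  rep_rows <- lapply(seq_len(nrep), function(r) list())
  sig_rows <- list()
  ex_by_gene <- split(annotation$exons, annotation$exons$gene_id)
  cat_genes <- catalog$genes
  site_by_gene <- if (!is.null(catalog$sites))
    split(catalog$sites, catalog$sites$gene_id) else list()

  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    span <- seq.int(g$start, g$end)
    mu <- rep(config$background_rate, length(span))
    cls <- cat_genes$class[match(g$gene_id, cat_genes$gene_id)]
    psi <- cat_genes$psi_ctl_mean[match(g$gene_id, cat_genes$gene_id)]
    ex <- ex_by_gene[[g$gene_id]]
    ord <- if (g$strand == "+") order(ex$start) else order(-ex$start)
    ex <- ex[ord, , drop = FALSE]
    alt <- ex[g$alt_exon_number, ]
    # abundance bias: more included exons carry more crosslink signal
    mu[(alt$start:alt$end) - g$start + 1L] <-
      mu[(alt$start:alt$end) - g$start + 1L] * (0.25 + 1.5 * psi)
    if (identical(cls, "down")) {
      idx <- (alt$start:alt$end) - g$start + 1L
      mu[idx] <- mu[idx] * config$region_enrichment
    } else if (identical(cls, "up")) {
      for (j in c(g$alt_exon_number - 1L, g$alt_exon_number + 1L)) {
        fx <- ex[j, ]
        idx <- (fx$start:fx$end) - g$start + 1L
        mu[idx] <- mu[idx] * config$region_enrichment
      }
    }
    ps <- site_by_gene[[g$gene_id]]
    if (!is.null(ps)) for (j in seq_len(nrow(ps))) {
      run <- ps$run_start[j]:ps$run_end[j]
      ramp <- seq(0.5, 1.5, length.out = length(run))
      if (g$strand == "-") ramp <- rev(ramp)  # peak at 3' end of the run
      mult <- 1 + (config$enrichment_factor - 1) * ramp *
        (0.5 + 0.25 * ps$n_triplets[j])
      idx <- run - g$start + 1L
      mu[idx] <- mu[idx] * mult
    }

    with_seed(substream_seed(config$seed, i, "counts"), {
      merged <- integer(length(span))
      for (r in seq_len(nrep)) {
        cnt <- stats::rnbinom(length(span), size = config$dispersion, mu = mu)
        merged <- merged + cnt
        nz <- cnt > 0L
        if (any(nz)) rep_rows[[r]][[length(rep_rows[[r]]) + 1L]] <- data.frame(
          chrom = g$chrom, pos = span[nz], strand = g$strand, count = cnt[nz],
          stringsAsFactors = FALSE)
      }
      thr <- quantile7(merged, config$background_quantile)
      sig <- merged > thr & merged > 0L
      if (any(sig)) sig_rows[[length(sig_rows) + 1L]] <- data.frame(
        chrom = g$chrom, pos = span[sig], strand = g$strand,
        score = merged[sig], stringsAsFactors = FALSE)
    })
  }

  replicates <- lapply(seq_len(nrep), function(r) {
    df <- do.call(rbind, rep_rows[[r]])
    if (is.null(df)) crosslink_track(replicate = paste0("rep", r))
    else crosslink_track(df$chrom, df$pos, df$strand, df$count,
                         replicate = paste0("rep", r))
  })
  merged <- merge_tracks(replicates)
  sdf <- do.call(rbind, sig_rows)
  sites <- if (is.null(sdf)) sig_sites()
  else sig_sites(sdf$chrom, sdf$pos, sdf$strand, sdf$score)
  list(replicates = replicates, merged = merged, sites = sites)
}
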