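#' Position-dependent RNA splicing maps with PSI-matched backgrounds
#'
#' For each regulated cassette-exon set, crosslink occupancy (fraction of
#' events with at least one crosslink event per position) is profiled in
#' symmetric windows around the six splice-site anchors of each event: the
#' 3' and 5' splice sites of the upstream constitutive, alternative and
#' downstream constitutive exon. A background set matched on the control-PSI
#' distribution is repeatedly subsampled from the unchanged pool; the mean
#' and SD of the background profiles yield positional z-scores, one-sided
#' p-values and Benjamini-Hochberg adjusted p-values.
#'
#' @name splicing_map
NULL

anchor_names <- c("up_3ss", "up_5ss", "alt_3ss", "alt_5ss",
                  "down_3ss", "down_5ss")

#' Splice-site anchors of cassette-exon events
#'
#' Anchor positions are the terminal exonic nucleotides: the 3' splice site
#' of an exon is its transcript-orientation first base, the 5' splice site
#' its last base (strand-aware).
#'
#' @param events A `ce_events` data.frame.
#' @return Data.frame `event_id`, `chrom`, `strand`, `anchor`, `pos`, six
#'   rows per event.
#' @export
splice_site_anchors <- function(events) {
  plus <- events$strand == "+"
  pos <- cbind(
    up_3ss = ifelse(plus, events$up_start, events$up_end),
    up_5ss = ifelse(plus, events$up_end, events$up_start),
    alt_3ss = ifelse(plus, events$alt_start, events$alt_end),
    alt_5ss = ifelse(plus, events$alt_end, events$alt_start),
    down_3ss = ifelse(plus, events$down_start, events$down_end),
    down_5ss = ifelse(plus, events$down_end, events$down_start))
  data.frame(event_id = rep(events$event_id, times = 6L),
             chrom = rep(events$chrom, times = 6L),
             strand = rep(events$strand, times = 6L),
             anchor = rep(anchor_names, each = nrow(events)),
             pos = as.integer(pos),
             stringsAsFactors = FALSE)
}

# Per-anchor logical indicator matrices (events x offsets -w..w): TRUE where
# the event has >= 1 crosslink event at that transcript-orientation offset.
event_anchor_indicators <- function(events, track, window = 100) {
  n <- nrow(events)
  offs <- seq(-window, window)
  tgr <- GenomicRanges::GRanges(track$chrom,
                                IRanges::IRanges(track$pos, width = 1L),
                                strand = track$strand)
  anchors <- splice_site_anchors(events)
  out <- list()
  for (a in anchor_names) {
    an <- anchors[anchors$anchor == a, , drop = FALSE]
    m <- matrix(FALSE, n, length(offs),
                dimnames = list(NULL, as.character(offs)))
    if (n > 0L && nrow(track) > 0L) {
      w <- GenomicRanges::GRanges(an$chrom,
                                  IRanges::IRanges(pmax(1L, an$pos - window),
                                                   an$pos + window),
                                  strand = an$strand)
      hits <- GenomicRanges::findOverlaps(w, tgr)
      if (length(hits)) {
        qh <- S4Vectors::queryHits(hits)
        tp <- track$pos[S4Vectors::subjectHits(hits)]
        off <- ifelse(an$strand[qh] == "+", tp - an$pos[qh],
                      an$pos[qh] - tp)
        keep <- abs(off) <= window
        m[cbind(qh[keep], off[keep] + window + 1L)] <- TRUE
      }
    }
    out[[a]] <- m
  }
  out
}

#' Crosslink occupancy profile around splice-site anchors
#'
#' @param events A `ce_events` set.
#' @param merged_track Merged `crosslink_track`.
#' @param window Half-window in nt (default 100: a symmetric 200-nt window).
#' @return Long data.frame `anchor`, `offset`, `fraction` (fraction of events
#'   with >= 1 crosslink event at that offset).
#' @export
occupancy_profile <- function(events, merged_track, window = 100) {
  ind <- event_anchor_indicators(events, merged_track, window)
  do.call(rbind, lapply(anchor_names, function(a) {
    data.frame(anchor = a, offset = seq(-window, window),
               fraction = if (nrow(events)) colMeans(ind[[a]]) else
                 rep(0, 2 * window + 1),
               stringsAsFactors = FALSE)
  }))
}

#' Sample a PSI-matched background set
#'
#' The regulated set's control-PSI distribution is split into `n_bins`
#' quantile bins (5% quantiles by default) and the same number of background
#' events is drawn, without replacement, from each bin of the pool. Bins
#' with too few pool events fall back to sampling with replacement (with a
#' warning).
#'
#' @param regulated_psi Control-PSI values of the regulated set.
#' @param pool_psi Control-PSI values of the background pool.
#' @param n_bins Number of quantile bins (default 20).
#' @param seed Integer seed.
#' @return Integer indices into the pool, of length
#'   `length(regulated_psi)`.
#' @export
psi_matched_sample <- function(regulated_psi, pool_psi, n_bins = 20,
                               seed = 1) {
  br <- unique(quantile7(regulated_psi, seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2L) br <- c(br - 1e-9, br + 1e-9)
  reg_bin <- cut(regulated_psi, br, include.lowest = TRUE)
  pool_bin <- cut(pool_psi, br, include.lowest = TRUE)
  need <- table(reg_bin)
  with_seed(seed, {
    idx <- integer(0)
    for (b in names(need)) {
      k <- need[[b]]
      if (k == 0L) next
      cand <- which(pool_bin == b)
      if (length(cand) >= k) {
        idx <- c(idx, cand[sample.int(length(cand), k)])
      } else if (length(cand) > 0L) {
        warning(sprintf(
          "PSI bin %s: pool has %d events for %d draws; sampling with replacement",
          b, length(cand), k))
        idx <- c(idx, cand[sample.int(length(cand), k, replace = TRUE)])
      } else {
        # empty bin: fall back to the pool events nearest in PSI
        warning(sprintf(
          "PSI bin %s: no pool events; drawing nearest-PSI events", b))
        mid <- mean(range(regulated_psi[reg_bin == b]))
        near <- order(abs(pool_psi - mid))[seq_len(k)]
        idx <- c(idx, near)
      }
    }
    idx
  })
}

#' Build the RNA splicing map for regulated cassette-exon sets
#'
#' For the down- and up-regulated sets separately: the observed occupancy
#' profile is compared against `n_iter` PSI-matched background subsamples of
#' the unchanged pool. Per anchor and offset, `z = (f_obs - mean_bg) /
#' sd_bg`; one-sided upper-tail p-values (standard normal, or the empirical
#' rank among background iterations with `pvalue = "empirical"`) are BH
#' adjusted across all positions of the set's map. Positions with zero
#' background SD get `z = 0`, `p = 1` and are flagged. A position is
#' significant when `z > 0` and the adjusted p-value is below `alpha`.
#'
#' @param sets A `regulated_sets` object (down/up/unchanged).
#' @param merged_track Merged `crosslink_track`.
#' @param n_iter Background subsampling iterations (default 50).
#' @param seed Integer seed.
#' @param alpha Significance level on adjusted p-values.
#' @param window Half-window around each anchor (default 100).
#' @param n_bins PSI-matching quantile bins.
#' @param pvalue `"normal"` or `"empirical"`.
#' @return A `splicing_map` data.frame: `set`, `anchor`, `offset`, `f_obs`,
#'   `bg_mean`, `bg_sd`, `z`, `p`, `padj`, `significant`, `sd_zero`, with
#'   `n_iter` and `seed` attributes.
#' @export
build_splicing_map <- function(sets, merged_track, n_iter = 50, seed = 1,
                               alpha = 0.05, window = 100, n_bins = 20,
                               pvalue = c("normal", "empirical")) {
  pvalue <- match.arg(pvalue)
  pool <- sets$unchanged
  if (nrow(pool) == 0L) stopf("empty background pool")
  pool_ind <- event_anchor_indicators(pool, merged_track, window)
  out <- list()
  for (set_name in c("down", "up")) {
    ev <- sets[[set_name]]
    if (nrow(ev) == 0L) next
    obs_ind <- event_anchor_indicators(ev, merged_track, window)
    f_obs <- unlist(lapply(anchor_names, function(a) colMeans(obs_ind[[a]])),
                    use.names = FALSE)
    bg <- matrix(NA_real_, n_iter, length(f_obs))
    bin_warnings <- character(0)
    withCallingHandlers(
      for (it in seq_len(n_iter)) {
        idx <- psi_matched_sample(ev$psi_ctl_mean, pool$psi_ctl_mean, n_bins,
                                  seed = substream_seed(seed, it,
                                                        paste0("bg_", set_name)))
        bg[it, ] <- unlist(lapply(anchor_names, function(a)
          colMeans(pool_ind[[a]][idx, , drop = FALSE])), use.names = FALSE)
      },
      warning = function(w) {
        bin_warnings <<- unique(c(bin_warnings, conditionMessage(w)))
        invokeRestart("muffleWarning")
      })
    if (length(bin_warnings))
      warning(sprintf("%s map: %d PSI bin(s) needed fallback sampling",
                      set_name, length(bin_warnings)))
    mu <- colMeans(bg)
    sd <- apply(bg, 2L, stats::sd)
    sd_zero <- sd == 0
    z <- ifelse(sd_zero, 0, (f_obs - mu) / sd)
    p <- if (pvalue == "normal") {
      ifelse(sd_zero, 1, stats::pnorm(z, lower.tail = FALSE))
    } else {
      ifelse(sd_zero, 1,
             (1 + colSums(sweep(bg, 2L, f_obs, `>=`))) / (n_iter + 1))
    }
    padj <- stats::p.adjust(p, method = "BH")
    out[[set_name]] <- data.frame(
      set = set_name,
      anchor = rep(anchor_names, each = 2L * window + 1L),
      offset = rep(seq(-window, window), times = length(anchor_names)),
      f_obs = f_obs, bg_mean = mu, bg_sd = sd, z = z, p = p, padj = padj,
      significant = z > 0 & padj < alpha, sd_zero = sd_zero,
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  attr(res, "n_iter") <- n_iter
  attr(res, "seed") <- seed
  class(res) <- c("splicing_map", "data.frame")
  res
}

#' Length-normalized crosslink density of exons
#'
#' `log2((events + pseudocount) / length)` per exon; used to demonstrate the
#' inclusion-level coverage bias that motivates PSI matching.
#'
#' @param exons Data.frame with `chrom`, `start`, `end`, `strand`.
#' @param merged_track Merged `crosslink_track`.
#' @param pseudocount Added to the event sum (default 1).
#' @return Numeric vector of densities.
#' @export
exon_crosslink_density <- function(exons, merged_track, pseudocount = 1) {
  sums <- track_interval_sums(merged_track, exons)
  log2((sums + pseudocount) / (exons$end - exons$start + 1))
}
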