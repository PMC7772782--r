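#' Binding-site definition from significant crosslink sites
#'
#' Turns scored single-nucleotide significant crosslink sites plus
#' crosslink-event tracks into equal-sized (9-nt), non-overlapping,
#' summit-centered, replicate-reproducible binding sites:
#'
#' 1. drop the 5% lowest-scoring sites ([filter_low_scores()]);
#' 2. cluster sites closer than 8 nt into regions, discard regions narrower
#'    than 3 nt ([cluster_sites()]);
#' 3. resolve regions into 9-nt windows centered on crosslink-event summits,
#'    extending short regions and iteratively splitting long ones, requiring
#'    at least two significant positions per site ([define_binding_sites()]);
#' 4. keep sites supported by at least three of four replicates at
#'    per-replicate 20%-quantile count thresholds
#'    ([reproducibility_filter()]).
#'
#' @name binding_sites
NULL

#' Drop the lowest-scoring significant sites
#'
#' Removes sites whose score falls below the `drop_fraction` quantile
#' (type-7) of all scores; sites scoring exactly at the cutoff are kept.
#'
#' @param sites A `sig_sites` table.
#' @param drop_fraction Fraction of lowest scores to remove (default 0.05).
#' @return The filtered `sig_sites`.
#' @export
filter_low_scores <- function(sites, drop_fraction = 0.05) {
  if (nrow(sites) == 0L) return(sites)
  thr <- quantile7(sites$score, drop_fraction)
  sites[sites$score >= thr, , drop = FALSE]
}

#' Cluster significant sites into candidate regions
#'
#' Consecutive sites on the same chromosome and strand with positional
#' distance strictly less than `max_distance` nt are joined into one region
#' spanning the first to the last site; regions narrower than `min_width` nt
#' are discarded.
#'
#' @param sites A `sig_sites` table.
#' @param max_distance Clustering distance (default 8: "closer than 8 nt").
#' @param min_width Minimum region width kept (default 3).
#' @return Data.frame of regions (`chrom`, `start`, `end`, `strand`,
#'   `n_sites`).
#' @export
cluster_sites <- function(sites, max_distance = 8, min_width = 3) {
  if (nrow(sites) == 0L)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      n_sites = integer(), stringsAsFactors = FALSE))
  parts <- split(sites, paste(sites$chrom, sites$strand))
  out <- lapply(parts, function(p) {
    pos <- sort(p$pos)
    grp <- cumsum(c(1L, as.integer(diff(pos) >= max_distance)))
    data.frame(chrom = p$chrom[1],
               start = tapply(pos, grp, min),
               end = tapply(pos, grp, max),
               strand = p$strand[1],
               n_sites = as.integer(table(grp)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  out <- out[out$end - out$start + 1L >= min_width, , drop = FALSE]
  out <- out[order(out$chrom, out$strand, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Summit tie-break: 5'-most maximal position in transcript orientation
# (leftmost on +, rightmost on -).
tie_argmax <- function(v, strand) {
  idx <- which(v == max(v))
  if (strand == "+") idx[1] else idx[length(idx)]
}

#' Resolve candidate regions into 9-nt summit-centered binding sites
#'
#' Regions narrower than `width` are extended symmetrically around their
#' crosslink-event summit; regions wider than `width` are split iteratively,
#' placing a window at the current global summit, masking it, and repeating
#' while some region position has a nonzero merged count and a would-be
#' window with at least `min_sig` significant positions that does not
#' overlap an already placed site. Width-`width` regions are emitted
#' unchanged with their summit as center. Sites whose window would leave the
#' chromosome are dropped with a warning; sites with fewer than `min_sig`
#' significant positions are discarded.
#'
#' @param regions Regions from [cluster_sites()].
#' @param merged_track Merged `crosslink_track`.
#' @param sites The filtered `sig_sites` (for significant-position counts and
#'   site scores).
#' @param width Binding-site width (odd; default 9).
#' @param min_sig Minimum significant positions per site (default 2).
#' @param chrom_lengths Optional named vector of chromosome lengths for
#'   right-boundary checks.
#' @return A `binding_sites` data.frame: `chrom`, `start`, `end`, `strand`,
#'   `center` (summit position), `score` (max site score in the window),
#'   `strength` (log2 score), `n_sig`, `site_id`.
#' @export
define_binding_sites <- function(regions, merged_track, sites, width = 9,
                                 min_sig = 2, chrom_lengths = NULL) {
  stopifnot(width %% 2 == 1)
  w2 <- (width - 1L) %/% 2L
  track_parts <- split(as.data.frame(merged_track),
                       paste(merged_track$chrom, merged_track$strand))
  site_parts <- split(as.data.frame(sites), paste(sites$chrom, sites$strand))
  out <- list()
  dropped_bounds <- 0L
  for (key in unique(paste(regions$chrom, regions$strand))) {
    rg <- regions[paste(regions$chrom, regions$strand) == key, , drop = FALSE]
    rg <- rg[order(rg$start), , drop = FALSE]
    strand <- rg$strand[1]; chrom <- rg$chrom[1]
    trk <- track_parts[[key]]
    spos <- sort(site_parts[[key]]$pos)
    sscore <- site_parts[[key]]$score[order(site_parts[[key]]$pos)]
    clen <- if (!is.null(chrom_lengths)) chrom_lengths[[chrom]] else Inf
    count_at <- function(lo, hi) {
      v <- integer(hi - lo + 1L)
      if (!is.null(trk)) {
        sel <- trk$pos >= lo & trk$pos <= hi
        v[trk$pos[sel] - lo + 1L] <- trk$count[sel]
      }
      v
    }
    nsig_in <- function(s, e) sum(spos >= s & spos <= e)
    score_in <- function(s, e) {
      sel <- spos >= s & spos <= e
      if (any(sel)) max(sscore[sel]) else NA_real_
    }
    placed_end <- -Inf  # regions processed left to right; windows too
    emit <- function(s, e, center) {
      if (s < 1L || e > clen) {
        dropped_bounds <<- dropped_bounds + 1L
        return(FALSE)
      }
      if (s <= placed_end) return(FALSE)  # global strand-wise non-overlap
      ns <- nsig_in(s, e)
      if (ns < min_sig) return(FALSE)
      placed_end <<- e
      out[[length(out) + 1L]] <<- data.frame(
        chrom = chrom, start = as.integer(s), end = as.integer(e),
        strand = strand, center = as.integer(center),
        score = score_in(s, e), n_sig = ns, stringsAsFactors = FALSE)
      TRUE
    }
    for (i in seq_len(nrow(rg))) {
      rs <- rg$start[i]; re <- rg$end[i]
      rw <- re - rs + 1L
      cnt <- count_at(rs, re)
      if (rw <= width) {
        summit <- rs + tie_argmax(cnt, strand) - 1L
        if (rw == width) emit(rs, re, summit)
        else emit(summit - w2, summit + w2, summit)
      } else {
        masked <- rep(FALSE, rw)
        repeat {
          cand <- which(!masked & cnt > 0L)
          if (length(cand)) {
            ok <- vapply(cand, function(j) {
              p <- rs + j - 1L
              s <- p - w2; e <- p + w2
              s > placed_end && s >= 1L && e <= clen &&
                nsig_in(s, e) >= min_sig
            }, NA)
            cand <- cand[ok]
          }
          if (!length(cand)) break
          j <- cand[tie_argmax(cnt[cand], strand)]
          p <- rs + j - 1L
          emit(p - w2, p + w2, p)
          masked[pmax(1L, j - w2):pmin(rw, j + w2)] <- TRUE
        }
      }
    }
  }
  if (dropped_bounds > 0L)
    warning(sprintf("%d site(s) dropped: window would leave the chromosome",
                    dropped_bounds))
  bs <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               strand = character(), center = integer(), score = numeric(),
               n_sig = integer(), stringsAsFactors = FALSE)
  bs <- bs[order(bs$chrom, bs$strand, bs$start), , drop = FALSE]
  rownames(bs) <- NULL
  bs$strength <- site_strength(bs$score)
  bs$site_id <- sprintf("BS%06d", seq_len(nrow(bs)))
  class(bs) <- c("binding_sites", "data.frame")
  bs
}

#' Binding-site strength
#'
#' The log2-transformed peak-caller score of a site (its maximum
#' significant-site score).
#'
#' @param score Positive score(s).
#' @return `log2(score)`.
#' @export
site_strength <- function(score) {
  if (any(!is.na(score) & score <= 0))
    stopf("site strength is undefined for score <= 0")
  log2(score)
}

#' Replicate-reproducibility filter for binding sites
#'
#' For each replicate, its support threshold is the `quantile` (default 20%)
#' type-7 quantile of the distribution of that replicate's crosslink events
#' summed within each binding site, over all binding sites. A site is
#' supported by a replicate when its summed events reach the threshold
#' (`>=`, or `>` with `strict = TRUE`), and retained when supported by at
#' least `min_support` replicates.
#'
#' @param binding_sites A `binding_sites` table.
#' @param replicate_tracks List of per-replicate `crosslink_track`s.
#' @param min_support Minimum supporting replicates (default 3 of 4).
#' @param quantile Quantile defining the per-replicate threshold.
#' @param strict Use strict `>` comparison instead of `>=`.
#' @return The retained sites, with per-replicate count columns
#'   (`events_rep<i>`) and `n_support`.
#' @export
reproducibility_filter <- function(binding_sites, replicate_tracks,
                                   min_support = 3, quantile = 0.20,
                                   strict = FALSE) {
  if (length(replicate_tracks) < min_support)
    stopf("need at least %d replicate tracks", min_support)
  if (nrow(binding_sites) == 0L) return(binding_sites)
  support <- matrix(FALSE, nrow(binding_sites), length(replicate_tracks))
  for (r in seq_along(replicate_tracks)) {
    sums <- track_interval_sums(replicate_tracks[[r]], binding_sites)
    thr <- quantile7(sums, quantile)
    support[, r] <- if (strict) sums > thr else sums >= thr
    binding_sites[[paste0("events_rep", r)]] <- sums
  }
  binding_sites$n_support <- rowSums(support)
  out <- binding_sites[binding_sites$n_support >= min_support, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Run the full binding-site definition pipeline
#'
#' @param sites Raw `sig_sites` (peak-caller output).
#' @param merged_track Merged `crosslink_track`.
#' @param replicate_tracks List of replicate `crosslink_track`s.
#' @param drop_fraction,max_distance,width,min_sig,min_support,support_quantile,strict
#'   Stage parameters; see the stage functions.
#' @param chrom_lengths Optional named chromosome lengths.
#' @return The reproducible `binding_sites` table.
#' @export
call_binding_sites <- function(sites, merged_track, replicate_tracks,
                               drop_fraction = 0.05, max_distance = 8,
                               width = 9, min_sig = 2, min_support = 3,
                               support_quantile = 0.20, strict = FALSE,
                               chrom_lengths = NULL) {
  kept <- filter_low_scores(sites, drop_fraction)
  regions <- cluster_sites(kept, max_distance)
  bs <- define_binding_sites(regions, merged_track, kept, width, min_sig,
                             chrom_lengths)
  reproducibility_filter(bs, replicate_tracks, min_support, support_quantile,
                         strict)
}

#' Write binding sites as BED6 (+ companion TSV)
#'
#' BED name is the site id and the BED score is `round(100 * strength)`; the
#' companion TSV carries the full table.
#'
#' @param binding_sites A `binding_sites` table.
#' @param prefix Output path prefix (`<prefix>.bed`, `<prefix>.tsv`).
#' @export
write_binding_sites <- function(binding_sites, prefix) {
  bed <- data.frame(chrom = binding_sites$chrom,
                    start = binding_sites$start - 1L,
                    end = binding_sites$end,
                    name = binding_sites$site_id,
                    score = round(100 * binding_sites$strength),
                    strand = binding_sites$strand)
  utils::write.table(bed, paste0(prefix, ".bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(binding_sites), paste0(prefix, ".tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(prefix)
}
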