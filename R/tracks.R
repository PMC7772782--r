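#' Crosslink-event tracks and significant-site tables
#'
#' A crosslink track is a sparse strand-specific per-nucleotide count table:
#' a data.frame with columns `chrom`, `pos` (1-based), `strand` (`+`/`-`) and
#' `count` (positive integer), carrying a `replicate` attribute (a replicate
#' name or `"merged"`). Significant crosslink sites are single-nucleotide
#' tables with columns `chrom`, `pos`, `strand`, `score` (positive; the
#' peak-caller score).
#'
#' @param chrom,pos,strand,count Parallel vectors of nonzero positions.
#' @param replicate Replicate label.
#' @return A `crosslink_track` data.frame.
#' @export
crosslink_track <- function(chrom = character(), pos = integer(),
                            strand = character(), count = integer(),
                            replicate = "merged") {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), count = as.integer(count),
                   stringsAsFactors = FALSE)
  validate_track(df)
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "replicate") <- replicate
  class(df) <- c("crosslink_track", "data.frame")
  df
}

validate_track <- function(df) {
  stopifnot(all(c("chrom", "pos", "strand", "count") %in% names(df)))
  if (any(df$count < 0)) stopf("crosslink counts must be >= 0")
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  invisible(df)
}

#' Merge replicate crosslink tracks by positionwise summation
#'
#' @param tracks List of `crosslink_track` data.frames.
#' @return A merged `crosslink_track` (replicate label `"merged"`) whose count
#'   at every position is the sum over replicates.
#' @export
merge_tracks <- function(tracks) {
  all <- do.call(rbind, lapply(tracks, function(t) as.data.frame(t)))
  if (is.null(all) || nrow(all) == 0L) return(crosslink_track())
  key <- paste(all$chrom, all$strand, all$pos)
  s <- rowsum(all$count, key)
  parts <- strsplit(rownames(s), " ", fixed = TRUE)
  crosslink_track(chrom = vapply(parts, `[`, "", 1L),
                  strand = vapply(parts, `[`, "", 2L),
                  pos = as.integer(vapply(parts, `[`, "", 3L)),
                  count = s[, 1L], replicate = "merged")
}

#' Dense count vector of a track over an interval
#'
#' @param track A `crosslink_track`.
#' @param chrom,strand Location.
#' @param start,end 1-based closed interval.
#' @return Integer vector of per-nucleotide counts, length `end - start + 1`.
#' @export
track_counts <- function(track, chrom, strand, start, end) {
  v <- integer(end - start + 1L)
  sel <- track$chrom == chrom & track$strand == strand &
    track$pos >= start & track$pos <= end
  if (any(sel)) v[track$pos[sel] - start + 1L] <- track$count[sel]
  v
}

#' Sum of track counts within intervals
#'
#' Strand-aware interval sums via cumulative counts over the sorted sparse
#' positions of each (chromosome, strand) slice.
#'
#' @param track A `crosslink_track`.
#' @param intervals Data.frame with `chrom`, `start`, `end`, `strand`.
#' @return Numeric vector of per-interval count sums.
#' @export
track_interval_sums <- function(track, intervals) {
  if (nrow(intervals) == 0L) return(numeric(0))
  out <- numeric(nrow(intervals))
  if (nrow(track) == 0L) return(out)
  key_t <- paste(track$chrom, track$strand)
  key_i <- paste(intervals$chrom, intervals$strand)
  for (k in unique(key_i)) {
    sel <- key_t == k
    if (!any(sel)) next
    pos <- track$pos[sel]
    cnt <- track$count[sel]
    o <- order(pos)
    pos <- pos[o]
    cs <- cumsum(cnt[o])
    ii <- which(key_i == k)
    hi <- findInterval(intervals$end[ii], pos)
    lo <- findInterval(intervals$start[ii] - 1L, pos)
    out[ii] <- ifelse(hi > 0L, cs[pmax(hi, 1L)], 0) -
      ifelse(lo > 0L, cs[pmax(lo, 1L)], 0)
  }
  out
}

#' Significant crosslink site table
#'
#' @param chrom,pos,strand,score Parallel vectors; `score` must be positive
#'   (a PureCLIP-style peak-caller score).
#' @return A `sig_sites` data.frame.
#' @export
sig_sites <- function(chrom = character(), pos = integer(),
                      strand = character(), score = numeric()) {
  df <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                   strand = as.character(strand), score = as.numeric(score),
                   stringsAsFactors = FALSE)
  if (any(df$score <= 0)) stopf("significant-site scores must be > 0")
  if (!all(df$strand %in% c("+", "-"))) stopf("strand must be '+' or '-'")
  df <- df[order(df$chrom, df$strand, df$pos), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("sig_sites", "data.frame")
  df
}

#' Write / read strand-split bedGraph crosslink tracks
#'
#' One bedGraph file per strand (`<prefix>.plus.bedgraph`,
#' `<prefix>.minus.bedgraph`), as iCLIP pipelines conventionally emit.
#'
#' @param track A `crosslink_track`.
#' @param prefix File path prefix.
#' @return `write_track_bedgraph` returns the two file paths invisibly;
#'   `read_track_bedgraph` returns a `crosslink_track`.
#' @export
write_track_bedgraph <- function(track, prefix) {
  paths <- c(`+` = paste0(prefix, ".plus.bedgraph"),
             `-` = paste0(prefix, ".minus.bedgraph"))
  for (s in c("+", "-")) {
    sub <- track[track$strand == s, , drop = FALSE]
    gr <- GenomicRanges::GRanges(sub$chrom,
                                 IRanges::IRanges(sub$pos, width = 1L),
                                 score = sub$count)
    rtracklayer::export(gr, paths[[s]], format = "bedGraph")
  }
  invisible(paths)
}

#' @rdname write_track_bedgraph
#' @param replicate Replicate label for the track read back.
#' @export
read_track_bedgraph <- function(prefix, replicate = "merged") {
  out <- list()
  for (s in c("+", "-")) {
    path <- paste0(prefix, if (s == "+") ".plus.bedgraph" else ".minus.bedgraph")
    if (!file.exists(path)) next
    gr <- rtracklayer::import(path, format = "bedGraph")
    if (length(gr) == 0L) next
    # expand multi-nt bedGraph intervals to per-nucleotide rows
    n <- GenomicRanges::width(gr)
    pos <- sequence(n, from = GenomicRanges::start(gr))
    out[[s]] <- data.frame(
      chrom = rep(as.character(GenomicRanges::seqnames(gr)), n),
      pos = pos, strand = s, count = rep(gr$score, n),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, out)
  if (is.null(all)) return(crosslink_track(replicate = replicate))
  crosslink_track(all$chrom, all$pos, all$strand, all$count,
                  replicate = replicate)
}

#' Write / read significant crosslink sites as BED6
#'
#' Single-nucleotide BED intervals; the BED score column carries the caller
#' score.
#'
#' @param sites A `sig_sites` table.
#' @param path Output path.
#' @export
write_sig_sites_bed <- function(sites, path) {
  df <- data.frame(chrom = sites$chrom, start = sites$pos - 1L,
                   end = sites$pos, name = sprintf("xl%06d", seq_len(nrow(sites))),
                   score = sites$score, strand = sites$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_sig_sites_bed
#' @export
read_sig_sites_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "numeric", "character"))
  sig_sites(df$chrom, df$end, df$strand, df$score)
}
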