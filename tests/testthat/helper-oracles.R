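# Brute-force reference implementations and fixture builders. These are kept
# deliberately naive and independent of the package's vectorized code paths:
# plain loops, naive lookups, direct rule transcription.

# ---- binding-site definition oracle ----------------------------------------

oracle_quantile <- function(x, p) unname(stats::quantile(x, p, type = 7))

# Full pipeline oracle: score filter -> clustering -> extend/split ->
# min-sig -> replicate support. Returns a data.frame like the package's
# binding_sites (chrom/start/end/strand/center only).
oracle_call_binding_sites <- function(sites, merged, reps,
                                      drop_fraction = 0.05, max_distance = 8,
                                      width = 9, min_sig = 2, min_support = 3,
                                      support_quantile = 0.20,
                                      chrom_len = Inf) {
  w2 <- (width - 1) / 2
  count_map <- stats::setNames(merged$count,
                               paste(merged$chrom, merged$strand, merged$pos))
  count_of <- function(chrom, strand, p) {
    v <- count_map[paste(chrom, strand, p)]
    if (is.na(v)) 0L else unname(v)
  }
  thr <- oracle_quantile(sites$score, drop_fraction)
  sites <- sites[sites$score >= thr, , drop = FALSE]

  placed <- list()
  for (strand in c("+", "-")) for (chrom in unique(sites$chrom)) {
    ss <- sites[sites$chrom == chrom & sites$strand == strand, , drop = FALSE]
    if (nrow(ss) == 0) next
    pos <- sort(ss$pos)
    regions <- list(); cur <- c(pos[1], pos[1])
    for (p in pos[-1]) {
      if (p - cur[2] < max_distance) cur[2] <- p
      else { regions[[length(regions) + 1]] <- cur; cur <- c(p, p) }
    }
    regions[[length(regions) + 1]] <- cur
    regions <- Filter(function(r) r[2] - r[1] + 1 >= 3, regions)

    nsig <- function(s, e) sum(pos >= s & pos <= e)
    last_end <- -Inf
    for (r in regions) {
      rw <- r[2] - r[1] + 1
      rpos <- r[1]:r[2]
      rcnt <- vapply(rpos, function(p) count_of(chrom, strand, p), 0L)
      summit_of <- function(idx) {
        mx <- idx[rcnt[idx] == max(rcnt[idx])]
        if (strand == "+") mx[1] else mx[length(mx)]
      }
      try_place <- function(s, e, center) {
        if (s < 1 || e > chrom_len) return(FALSE)
        if (s <= last_end) return(FALSE)
        if (nsig(s, e) < min_sig) return(FALSE)
        placed[[length(placed) + 1]] <<- data.frame(
          chrom = chrom, start = s, end = e, strand = strand,
          center = center, stringsAsFactors = FALSE)
        last_end <<- e
        TRUE
      }
      if (rw < width) {
        smt <- rpos[summit_of(seq_along(rpos))]
        try_place(smt - w2, smt + w2, smt)
      } else if (rw == width) {
        try_place(r[1], r[2], rpos[summit_of(seq_along(rpos))])
      } else {
        masked <- rep(FALSE, rw)
        repeat {
          ok <- which(!masked & rcnt > 0)
          ok <- ok[vapply(ok, function(j) {
            p <- rpos[j]
            p - w2 > last_end && p - w2 >= 1 && p + w2 <= chrom_len &&
              nsig(p - w2, p + w2) >= min_sig
          }, NA)]
          if (!length(ok)) break
          j <- summit_of(ok)
          smt <- rpos[j]
          try_place(smt - w2, smt + w2, smt)
          masked[max(1, j - w2):min(rw, j + w2)] <- TRUE
        }
      }
    }
  }
  bs <- if (length(placed)) do.call(rbind, placed) else
    data.frame(chrom = character(), start = numeric(), end = numeric(),
               strand = character(), center = numeric())
  if (nrow(bs) == 0) return(bs)

  # replicate support, recomputed naively
  support <- matrix(FALSE, nrow(bs), length(reps))
  for (r in seq_along(reps)) {
    sums <- vapply(seq_len(nrow(bs)), function(i) {
      sel <- reps[[r]]$chrom == bs$chrom[i] &
        reps[[r]]$strand == bs$strand[i] &
        reps[[r]]$pos >= bs$start[i] & reps[[r]]$pos <= bs$end[i]
      sum(reps[[r]]$count[sel])
    }, 0)
    support[, r] <- sums >= oracle_quantile(sums, support_quantile)
  }
  bs <- bs[rowSums(support) >= min_support, , drop = FALSE]
  bs <- bs[order(bs$chrom, bs$strand, bs$start), , drop = FALSE]
  rownames(bs) <- NULL
  bs
}

# Random small instance on a toy chromosome (both strands).
random_bs_instance <- function(chrom_len = 600, n_rep = 4) {
  strand_sites <- function(strand) {
    n <- sample(5:40, 1)
    pos <- sort(sample(seq_len(chrom_len), n))
    data.frame(chrom = "toy", pos = pos, strand = strand,
               score = round(stats::runif(n, 0.5, 50), 3),
               stringsAsFactors = FALSE)
  }
  sites <- rbind(strand_sites("+"), strand_sites("-"))
  reps <- lapply(seq_len(n_rep), function(r) {
    rows <- do.call(rbind, lapply(c("+", "-"), function(strand) {
      n <- sample(30:120, 1)
      pos <- sample(seq_len(chrom_len), n)
      # bias counts towards significant-site neighbourhoods
      extra <- sample(sites$pos[sites$strand == strand],
                      min(10, sum(sites$strand == strand)))
      pos <- unique(c(pos, extra))
      data.frame(chrom = "toy", pos = pos, strand = strand,
                 count = stats::rnbinom(length(pos), size = 0.8, mu = 3) + 1L,
                 stringsAsFactors = FALSE)
    }))
    clipmap::crosslink_track(rows$chrom, rows$pos, rows$strand, rows$count,
                             replicate = paste0("rep", r))
  })
  merged <- clipmap::merge_tracks(reps)
  list(sites = clipmap::sig_sites(sites$chrom, sites$pos, sites$strand,
                                  sites$score),
       reps = reps, merged = merged, chrom_len = chrom_len)
}

# ---- pentamer oracles ------------------------------------------------------

oracle_pentamer_count <- function(seq) {
  counts <- integer(0)
  n <- nchar(seq)
  if (n >= 5) for (i in 1:(n - 4)) {
    p <- substr(seq, i, i + 4)
    counts[p] <- (if (is.na(counts[p])) 0L else counts[p]) + 1L
  }
  counts
}

# ---- misc ------------------------------------------------------------------

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", vapply(x, function(s)
    paste(rev(strsplit(s, "")[[1]]), collapse = ""), ""))
}

# Shared default synthetic study, built once per test run.
default_study <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- clipmap::simulate_study(
      clipmap::synth_config(seed = 1))
    cache
  }
})

# Minimal read builder with explicit qualities (Phred+33).
make_read <- function(id, seq, quals) {
  stopifnot(nchar(seq) == length(quals))
  data.frame(id = id, seq = seq,
             qual = intToUtf8(quals + 33L, multiple = FALSE),
             stringsAsFactors = FALSE)
}
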