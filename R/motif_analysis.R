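#' Motif analytics around binding sites
#'
#' Pentamer frequency comparisons between the 9-nt binding site and its
#' 20-nt flanks, 201-nt positional pentamer profiles with k-means
#' clustering, and GAA/UUC triplet counts versus binding-site strength in
#' 49-nt windows. Sequences are handled as DNA internally; [to_rna()]
#' converts motif labels to the RNA alphabet for presentation.
#'
#' @name motif_analysis
NULL

#' @rdname motif_analysis
#' @param x Character vector of DNA motifs.
#' @return `to_rna`: the motifs with T replaced by U.
#' @export
to_rna <- function(x) chartr("T", "U", x)

all_pentamers <- function() Biostrings::mkAllStrings(c("A", "C", "G", "T"), 5)

# Strand-aware sense-sequence extraction for genomic intervals. Intervals
# outside the chromosome are returned as NA.
extract_seqs <- function(genome, chrom, start, end, strand) {
  chars <- as.character(genome)
  clen <- nchar(chars)[match(chrom, names(chars))]
  ok <- !is.na(clen) & start >= 1L & end <= clen
  out <- rep(NA_character_, length(chrom))
  out[ok] <- substring(chars[chrom[ok]], start[ok], end[ok])
  neg <- ok & strand == "-"
  if (any(neg))
    out[neg] <- as.character(
      Biostrings::reverseComplement(Biostrings::DNAStringSet(out[neg])))
  out
}

#' Randomly sample binding sites per transcript region
#'
#' Uniform sample without replacement of up to `per_region_n` sites from
#' each region class; classes with fewer sites contribute all of them.
#'
#' @param binding_sites Binding sites with a `region` column (from
#'   [assign_region()]).
#' @param per_region_n Sites sampled per region class (default 5000).
#' @param seed Integer seed.
#' @return The sampled subset.
#' @export
sample_sites <- function(binding_sites, per_region_n = 5000, seed = 1) {
  with_seed(seed, {
    keep <- unlist(lapply(split(seq_len(nrow(binding_sites)),
                                binding_sites$region), function(idx) {
      if (length(idx) <= per_region_n) idx
      else sample(idx, per_region_n)
    }), use.names = FALSE)
    out <- binding_sites[sort(keep), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Mean pentamer counts in binding sites and their flanks
#'
#' Overlapping pentamer occurrences are counted in the binding site itself
#' and in the `flank`-nt windows immediately up- and downstream (transcript
#' orientation; minus-strand sites are reverse-complemented), then averaged
#' over sites. When the input carries a `region` column the means are
#' reported per region class.
#'
#' @param binding_sites Binding-site table (columns `chrom`, `start`, `end`,
#'   `strand`, optionally `region`).
#' @param genome `DNAStringSet`.
#' @param flank Flank width in nt (default 20).
#' @return Long data.frame: `region`, `pentamer`, `site_mean`, `up_mean`,
#'   `down_mean`.
#' @export
pentamer_window_counts <- function(binding_sites, genome, flank = 20) {
  bs <- binding_sites
  plus <- bs$strand == "+"
  up_s <- ifelse(plus, bs$start - flank, bs$end + 1L)
  up_e <- ifelse(plus, bs$start - 1L, bs$end + flank)
  dn_s <- ifelse(plus, bs$end + 1L, bs$start - flank)
  dn_e <- ifelse(plus, bs$end + flank, bs$start - 1L)
  windows <- list(
    site = extract_seqs(genome, bs$chrom, bs$start, bs$end, bs$strand),
    up = extract_seqs(genome, bs$chrom, up_s, up_e, bs$strand),
    down = extract_seqs(genome, bs$chrom, dn_s, dn_e, bs$strand))
  cls <- if ("region" %in% names(bs)) bs$region else rep("all", nrow(bs))
  out <- lapply(unique(cls), function(cl) {
    idx <- which(cls == cl)
    means <- lapply(windows, function(w) {
      w <- w[idx]; w <- w[!is.na(w)]
      if (!length(w)) return(stats::setNames(rep(NA_real_, 4^5),
                                             all_pentamers()))
      colMeans(Biostrings::oligonucleotideFrequency(
        Biostrings::DNAStringSet(w), width = 5))
    })
    data.frame(region = cl, pentamer = all_pentamers(),
               site_mean = unname(means$site), up_mean = unname(means$up),
               down_mean = unname(means$down), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Positional pentamer occurrence profiles around binding-site centers
#'
#' For each offset in `-100..+100` (pentamer start position relative to the
#' site center, transcript orientation), the fraction of binding sites whose
#' pentamer starting at that offset equals the given pentamer. Offsets too
#' close to the window's 3' edge to hold a full pentamer have frequency 0;
#' over covered offsets the 1,024 frequencies sum to 1. Sites whose window
#' would leave the chromosome are skipped.
#'
#' @param binding_sites Binding-site table with a `center` column.
#' @param genome `DNAStringSet`.
#' @param window Window width in nt (odd; default 201).
#' @return Numeric matrix, pentamers x offsets (`-100` .. `100`), with an
#'   `n_sites` attribute.
#' @export
positional_profiles <- function(binding_sites, genome, window = 201) {
  stopifnot(window %% 2 == 1)
  w2 <- (window - 1L) %/% 2L
  ctr <- binding_sites$center
  seqs <- extract_seqs(genome, binding_sites$chrom, ctr - w2, ctr + w2,
                       binding_sites$strand)
  seqs <- seqs[!is.na(seqs)]
  pent <- all_pentamers()
  prof <- matrix(0, nrow = length(pent), ncol = window,
                 dimnames = list(pent, as.character(seq(-w2, w2))))
  n <- length(seqs)
  if (n > 0L) {
    for (k in seq_len(window - 4L)) {
      tab <- table(factor(substring(seqs, k, k + 4L), levels = pent))
      prof[, k] <- as.numeric(tab) / n
    }
  }
  attr(prof, "n_sites") <- n
  prof
}

#' Cluster positional profiles of the most frequent pentamers
#'
#' Ranks pentamers by their in-site frequency, takes the top `top_n`, and
#' k-means clusters their positional profiles (seeded, `nstart` restarts for
#' stability).
#'
#' @param profiles Matrix from [positional_profiles()].
#' @param site_freq Named numeric vector of in-site pentamer frequencies
#'   used for ranking (e.g. the `site_mean` column of
#'   [pentamer_window_counts()] for the CDS class).
#' @param k Number of clusters (default 3).
#' @param top_n Pentamers clustered (default 300).
#' @param seed Integer seed.
#' @param nstart k-means restarts.
#' @return Data.frame (`pentamer`, `site_freq`, `cluster`), ordered by
#'   cluster then descending frequency, with the `kmeans` fit as an
#'   attribute.
#' @export
cluster_profiles <- function(profiles, site_freq, k = 3, top_n = 300,
                             seed = 1, nstart = 10) {
  top <- names(sort(site_freq, decreasing = TRUE))[seq_len(min(top_n,
                                                               length(site_freq)))]
  top <- top[top %in% rownames(profiles)]
  m <- profiles[top, , drop = FALSE]
  fit <- with_seed(seed, stats::kmeans(m, centers = k, nstart = nstart,
                                       iter.max = 50))
  out <- data.frame(pentamer = top, site_freq = unname(site_freq[top]),
                    cluster = unname(fit$cluster), stringsAsFactors = FALSE)
  out <- out[order(out$cluster, -out$site_freq), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "kmeans") <- fit
  out
}

#' Count non-overlapping triplet occurrences in sequences
#'
#' Left-to-right maximal non-overlapping placements (for period-3 triplets
#' like GAA this equals the overlapping count).
#'
#' @param seqs Character vector of sequences.
#' @param triplet 3-nt DNA motif.
#' @return Integer vector of counts.
#' @export
count_triplets <- function(seqs, triplet) {
  vapply(gregexpr(triplet, seqs, fixed = TRUE), function(m)
    if (m[1] == -1L) 0L else length(m), 0L)
}

# Start positions of non-overlapping occurrences (integer(0) when absent).
triplet_starts <- function(seq, triplet) {
  m <- gregexpr(triplet, seq, fixed = TRUE)[[1]]
  if (m[1] == -1L) integer(0) else as.integer(m)
}

#' Triplet counts versus binding-site strength
#'
#' Counts GAA and UUC (scanned as TTC on the sense sequence) triplets in a
#' `window`-nt window centered on each binding site and joins them with the
#' site strength (log2 peak-caller score). `summarize_triplet_strength()`
#' gives per-count-category strength quartiles with counts capped at `7+`.
#'
#' @param binding_sites Binding-site table with `center` and `strength`.
#' @param genome `DNAStringSet`.
#' @param window Window width (odd; default 49).
#' @param triplets DNA triplets to count (named by presentation label).
#' @return Data.frame with one row per site: `site_id`, `strength`, one
#'   `n_<label>` column per triplet.
#' @export
triplet_strength_analysis <- function(binding_sites, genome, window = 49,
                                      triplets = c(GAA = "GAA", UUC = "TTC")) {
  stopifnot(window %% 2 == 1)
  w2 <- (window - 1L) %/% 2L
  seqs <- extract_seqs(genome, binding_sites$chrom,
                       binding_sites$center - w2, binding_sites$center + w2,
                       binding_sites$strand)
  out <- data.frame(site_id = binding_sites$site_id,
                    strength = binding_sites$strength,
                    stringsAsFactors = FALSE)
  for (lab in names(triplets))
    out[[paste0("n_", lab)]] <- count_triplets(seqs, triplets[[lab]])
  out[!is.na(seqs), , drop = FALSE]
}

#' @rdname triplet_strength_analysis
#' @param table Output of [triplet_strength_analysis()].
#' @param count_col Which count column to stratify on.
#' @param cap Counts at or above this collapse into a `"<cap>+"` category.
#' @export
summarize_triplet_strength <- function(table, count_col = "n_GAA", cap = 7) {
  n <- table[[count_col]]
  category <- ifelse(n >= cap, paste0(cap, "+"), as.character(n))
  category <- factor(category, levels = c(as.character(0:(cap - 1)),
                                          paste0(cap, "+")))
  agg <- split(table$strength, category)
  data.frame(category = names(agg),
             n_sites = vapply(agg, length, 0L),
             q25 = vapply(agg, function(v) if (length(v)) quantile7(v, .25) else NA_real_, 0),
             median = vapply(agg, function(v) if (length(v)) stats::median(v) else NA_real_, 0),
             q75 = vapply(agg, function(v) if (length(v)) quantile7(v, .75) else NA_real_, 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify binding sites by consecutive-triplet runs
#'
#' A chain at gap `g` is a series of triplet occurrences where successive
#' occurrences are separated by exactly `g` intervening nucleotides. Sites
#' are classified as `0-1` (fewer than two triplets), `ge2_direct`
#' (a chain of two or more directly adjacent triplets), `ge2_gap1`,
#' `ge2_gap2`, or `ge2_scattered` (two or more triplets but no chain at any
#' allowed gap); the first matching class in that order wins.
#'
#' @param binding_sites Binding-site table with `center`.
#' @param genome `DNAStringSet`.
#' @param window Window width (odd; default 49).
#' @param triplet DNA triplet (default GAA).
#' @param allowed_gaps Gap sizes defining the chain classes.
#' @return Data.frame with `site_id`, `n_triplets`, `run_gap<g>` columns
#'   (maximal chain length per gap) and `class`.
#' @export
consecutive_run_analysis <- function(binding_sites, genome, window = 49,
                                     triplet = "GAA",
                                     allowed_gaps = c(0, 1, 2)) {
  stopifnot(window %% 2 == 1)
  w2 <- (window - 1L) %/% 2L
  seqs <- extract_seqs(genome, binding_sites$chrom,
                       binding_sites$center - w2, binding_sites$center + w2,
                       binding_sites$strand)
  tl <- nchar(triplet)
  runs <- lapply(seqs, function(s) {
    if (is.na(s)) return(rep(NA_integer_, length(allowed_gaps)))
    st <- triplet_starts(s, triplet)
    vapply(allowed_gaps, function(g) max_chain(st, tl + g), 0L)
  })
  runs <- do.call(rbind, runs)
  colnames(runs) <- paste0("run_gap", allowed_gaps)
  n <- count_triplets(seqs, triplet)
  class <- rep("0-1", nrow(binding_sites))
  class[n >= 2L] <- "ge2_scattered"
  for (g in rev(allowed_gaps))
    class[!is.na(runs[, 1]) & runs[, paste0("run_gap", g)] >= 2L] <-
      if (g == 0) "ge2_direct" else paste0("ge2_gap", g)
  class[is.na(seqs)] <- NA_character_
  cbind(data.frame(site_id = binding_sites$site_id, n_triplets = n,
                   stringsAsFactors = FALSE),
        as.data.frame(runs), data.frame(class = class,
                                        stringsAsFactors = FALSE))
}

# Longest run of occurrence starts with consecutive differences == step.
max_chain <- function(starts, step) {
  if (length(starts) == 0L) return(0L)
  if (length(starts) == 1L) return(1L)
  d <- diff(starts) == step
  best <- run <- 1L
  for (x in d) {
    run <- if (x) run + 1L else 1L
    best <- max(best, run)
  }
  best
}

#' Simulate binding-site windows with planted triplet counts and strengths
#'
#' Builds `window`-nt sequences scrubbed of GAA and TTC, plants independent
#' numbers of GAA and TTC triplets (uniform on `0..max_triplets` each) at
#' disjoint slots, and assigns each site a strength
#' `a + b * n_GAA + Normal(0, noise_sd)` -- the generative model under which
#' stratified strength medians must rise with the GAA count while UUC counts
#' stay uninformative.
#'
#' @param n Number of sites.
#' @param a,b,noise_sd Strength model parameters (`b > 0`).
#' @param max_triplets Maximum planted count per triplet.
#' @param window Window width (default 49).
#' @param seed Integer seed.
#' @return Data.frame with `site_id`, `seq`, `n_gaa_planted`,
#'   `n_uuc_planted`, `strength`.
#' @export
simulate_motif_strength_sites <- function(n = 5000, a = 2, b = 0.8,
                                          noise_sd = 0.5, max_triplets = 7,
                                          window = 49, seed = 1) {
  slots <- seq(1L, window - 3L, by = 3L)
  stopifnot(length(slots) >= 2 * max_triplets)
  with_seed(seed, {
    n_gaa <- sample(0:max_triplets, n, replace = TRUE)
    n_uuc <- sample(0:max_triplets, n, replace = TRUE)
    seqs <- vapply(seq_len(n), function(i) {
      s <- paste(sample(c("A", "C", "G", "T"), window, replace = TRUE),
                 collapse = "")
      repeat {  # scrub pre-existing GAA/TTC occurrences
        hit <- regexpr("GAA|TTC", s)
        if (hit == -1L) break
        substr(s, hit + 1L, hit + 1L) <- "C"
      }
      pick <- sample(slots, n_gaa[i] + n_uuc[i])
      for (p in pick[seq_len(n_gaa[i])]) substr(s, p, p + 2L) <- "GAA"
      for (p in pick[n_gaa[i] + seq_len(n_uuc[i])]) substr(s, p, p + 2L) <- "TTC"
      s
    }, character(1))
    data.frame(site_id = sprintf("SIM%05d", seq_len(n)), seq = seqs,
               n_gaa_planted = n_gaa, n_uuc_planted = n_uuc,
               strength = a + b * n_gaa + stats::rnorm(n, 0, noise_sd),
               stringsAsFactors = FALSE)
  })
}
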