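toy_track <- function(pos, count, strand = "+", chrom = "toy") {
  crosslink_track(rep(chrom, length(pos)), pos, rep(strand, length(pos)),
                  count)
}
toy_sites <- function(pos, score = NULL, strand = "+", chrom = "toy") {
  sig_sites(rep(chrom, length(pos)), pos, rep(strand, length(pos)),
            score %||% rep(1, length(pos)))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("low-score filter removes the bottom fraction, keeping ties", {
  s <- toy_sites(seq(10, 1000, by = 10), score = 1:100)
  kept <- filter_low_scores(s, 0.05)
  expect_identical(nrow(kept), 95L)
  expect_identical(sort(kept$score), as.numeric(6:100))
  # all-equal scores: nothing removed
  eq <- toy_sites(c(10, 20, 30), score = c(7, 7, 7))
  expect_identical(nrow(filter_low_scores(eq)), 3L)
  expect_identical(nrow(filter_low_scores(toy_sites(integer(0),
                                                    numeric(0)))), 0L)
})

test_that("site clustering joins sites closer than 8 nt and drops <3 nt", {
  r <- cluster_sites(toy_sites(c(10, 12, 25)))
  expect_identical(nrow(r), 1L)
  expect_identical(c(r$start, r$end), c(10L, 12L))
  # distance 7 < 8: one region of width 8
  r2 <- cluster_sites(toy_sites(c(10, 17)))
  expect_identical(nrow(r2), 1L)
  expect_identical(r2$end - r2$start + 1L, 8L)
  # distance exactly 8 splits; isolated width-1 regions vanish
  expect_identical(nrow(cluster_sites(toy_sites(c(10, 18)))), 0L)
  expect_identical(nrow(cluster_sites(toy_sites(50))), 0L)
})

test_that("short regions extend to 9 nt around the summit", {
  sites <- toy_sites(c(20, 22, 24))
  track <- toy_track(c(20, 21, 22, 23, 24), c(1, 2, 7, 2, 1))
  bs <- define_binding_sites(cluster_sites(sites), track, sites)
  expect_identical(nrow(bs), 1L)
  expect_identical(bs$center, 22L)
  expect_identical(c(bs$start, bs$end), c(18L, 26L))
  expect_identical(bs$n_sig, 3L)
  # a width-5 region with 1 significant position is discarded after extension
  one <- toy_sites(c(30, 34))  # width-5 region, then drop one site
  reg <- cluster_sites(one)
  bs2 <- define_binding_sites(reg, toy_track(30:34, rep(2, 5)),
                              toy_sites(32), min_sig = 2)
  expect_identical(nrow(bs2), 0L)
})

test_that("long regions split iteratively at summits", {
  # 20-nt region with two summits 11 nt apart, >= 2 significant under each
  pos <- 30:49
  sites <- toy_sites(c(31, 33, 42, 44, 47))
  cnt <- rep(1, 20); cnt[pos == 33] <- 9; cnt[pos == 44] <- 8
  track <- toy_track(pos, cnt)
  bs <- define_binding_sites(cluster_sites(sites), track, sites)
  expect_identical(nrow(bs), 2L)
  expect_setequal(bs$center, c(33L, 44L))
  expect_true(all(bs$end - bs$start + 1L == 9L))
  # non-overlap
  expect_true(bs$start[2] > bs$end[1])
})

test_that("summit ties break 5'-wards in transcript orientation", {
  sites_p <- toy_sites(c(20, 24))
  track_p <- toy_track(c(20, 22, 24), c(3, 3, 3))
  bs_p <- define_binding_sites(cluster_sites(sites_p), track_p, sites_p)
  expect_identical(bs_p$center, 20L)
  sites_m <- toy_sites(c(20, 24), strand = "-")
  track_m <- toy_track(c(20, 22, 24), c(3, 3, 3), strand = "-")
  bs_m <- define_binding_sites(cluster_sites(sites_m), track_m, sites_m)
  expect_identical(bs_m$center, 24L)
})

test_that("sites whose window would leave the chromosome are dropped", {
  sites <- toy_sites(c(2, 4))
  track <- toy_track(c(2, 3, 4), c(1, 5, 1))
  expect_warning(
    bs <- define_binding_sites(cluster_sites(sites), track, sites,
                               chrom_lengths = c(toy = 1000)),
    "leave the chromosome")
  expect_identical(nrow(bs), 0L)
})

test_that("site strength is the log2 score and rejects score <= 0", {
  expect_identical(site_strength(8), 3)
  expect_identical(site_strength(1), 0)
  expect_error(site_strength(0), "undefined")
})

test_that("reproducibility filter matches an independent recomputation", {
  set.seed(42)
  inst <- random_bs_instance(chrom_len = 2000)
  bs <- suppressWarnings(define_binding_sites(
    cluster_sites(inst$sites), inst$merged, inst$sites,
    chrom_lengths = c(toy = inst$chrom_len)))
  expect_gt(nrow(bs), 2)
  kept <- reproducibility_filter(bs, inst$reps)
  # naive recomputation
  sums <- sapply(inst$reps, function(rep) {
    vapply(seq_len(nrow(bs)), function(i) {
      sel <- rep$chrom == bs$chrom[i] & rep$strand == bs$strand[i] &
        rep$pos >= bs$start[i] & rep$pos <= bs$end[i]
      sum(rep$count[sel])
    }, 0)
  })
  thr <- apply(sums, 2, function(v) unname(quantile(v, 0.2, type = 7)))
  manual <- rowSums(sweep(sums, 2, thr, `>=`)) >= 3
  expect_identical(kept$site_id, bs$site_id[manual])
  # a site with zero events everywhere is below any positive threshold
  if (any(rowSums(sums) == 0) && all(thr > 0))
    expect_false(any(kept$site_id %in% bs$site_id[rowSums(sums) == 0]))
})

test_that("three-of-four support retains sites with one zeroed replicate", {
  sites <- toy_sites(c(20, 22, 24, 120, 122, 124))
  track <- toy_track(c(20:24, 120:124), c(1, 2, 7, 2, 1, 1, 2, 7, 2, 1))
  bs0 <- define_binding_sites(cluster_sites(sites), track, sites)
  expect_identical(nrow(bs0), 2L)
  reps <- lapply(1:4, function(r) {
    # replicate 1 sees only the second site; its threshold stays positive
    if (r == 1) toy_track(120:124, rep(3, 5))
    else toy_track(c(20:24, 120:124), rep(3, 10))
  })
  kept <- reproducibility_filter(bs0, reps)
  expect_identical(nrow(kept), 2L)
  expect_identical(kept$n_support, c(3, 4))
})

test_that("pipeline output equals the brute-force oracle on random instances", {
  set.seed(1)
  n_instances <- 150
  for (i in seq_len(n_instances)) {
    inst <- random_bs_instance(chrom_len = sample(300:1000, 1))
    got <- suppressWarnings(call_binding_sites(
      inst$sites, inst$merged, inst$reps,
      chrom_lengths = c(toy = inst$chrom_len)))
    want <- suppressWarnings(oracle_call_binding_sites(
      as.data.frame(inst$sites), as.data.frame(inst$merged),
      lapply(inst$reps, as.data.frame), chrom_len = inst$chrom_len))
    got_key <- paste(got$chrom, got$strand, got$start, got$end, got$center)
    want_key <- paste(want$chrom, want$strand, want$start, want$end,
                      want$center)
    expect_identical(got_key, want_key)
  }
})

test_that("structural invariants hold on the synthetic study output", {
  st <- default_study()
  bs <- suppressWarnings(call_binding_sites(
    st$tracks$sites, st$tracks$merged, st$tracks$replicates,
    chrom_lengths = chrom_lengths(st$genome)))
  expect_gt(nrow(bs), 50)
  expect_true(all(bs$end - bs$start + 1L == 9L))
  expect_true(all(bs$center >= bs$start & bs$center <= bs$end))
  expect_true(all(bs$n_sig >= 2L))
  # strand-wise non-overlap
  by_strand <- split(bs, paste(bs$chrom, bs$strand))
  for (b in by_strand) {
    b <- b[order(b$start), ]
    if (nrow(b) > 1) expect_true(all(b$start[-1] > b$end[-nrow(b)]))
  }
  # center is an argmax of merged events among the admissible summit
  # positions of the site: positions of the source region inside the site
  # whose 9-nt window does not overlap any other emitted site (extension can
  # also pull in window positions outside the region; those never vote)
  kept_sites <- filter_low_scores(st$tracks$sites)
  regions <- cluster_sites(kept_sites)
  for (i in seq_len(nrow(bs))) {
    r <- regions[regions$chrom == bs$chrom[i] &
                   regions$strand == bs$strand[i] &
                   regions$start <= bs$center[i] &
                   regions$end >= bs$center[i], ]
    expect_identical(nrow(r), 1L)
    lo <- max(bs$start[i], r$start[1]); hi <- min(bs$end[i], r$end[1])
    others <- bs[-i, ]
    others <- others[others$chrom == bs$chrom[i] &
                       others$strand == bs$strand[i], ]
    sig_pos <- kept_sites$pos[kept_sites$chrom == bs$chrom[i] &
                                kept_sites$strand == bs$strand[i]]
    admissible <- Filter(function(p) {
      !any(p - 4L <= others$end & p + 4L >= others$start) &&
        sum(sig_pos >= p - 4L & sig_pos <= p + 4L) >= 2L
    }, lo:hi)
    cnt <- track_counts(st$tracks$merged, bs$chrom[i], bs$strand[i], lo, hi)
    expect_true(bs$center[i] %in% admissible)
    expect_identical(cnt[bs$center[i] - lo + 1L],
                     max(cnt[admissible - lo + 1L]))
  }
})

test_that("adding events at a retained site never drops it", {
  set.seed(99)
  for (rep_i in 1:10) {
    inst <- random_bs_instance(chrom_len = 800)
    bs <- suppressWarnings(define_binding_sites(
      cluster_sites(inst$sites), inst$merged, inst$sites,
      chrom_lengths = c(toy = inst$chrom_len)))
    kept <- reproducibility_filter(bs, inst$reps)
    if (nrow(kept) == 0) next
    pick <- kept[sample(nrow(kept), 1), ]
    boosted <- inst$reps
    r <- sample(length(boosted), 1)
    extra <- data.frame(chrom = pick$chrom, pos = pick$center,
                        strand = pick$strand, count = 50L)
    b <- rbind(as.data.frame(boosted[[r]]), extra)
    agg <- rowsum(b$count, paste(b$chrom, b$strand, b$pos))
    parts <- strsplit(rownames(agg), " ")
    boosted[[r]] <- crosslink_track(
      sapply(parts, `[`, 1), as.integer(sapply(parts, `[`, 3)),
      sapply(parts, `[`, 2), agg[, 1],
      replicate = attr(boosted[[r]], "replicate"))
    kept2 <- reproducibility_filter(bs, boosted)
    expect_true(pick$site_id %in% kept2$site_id)
  }
})
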