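mk_ev <- function(id, chrom = "chrT", strand = "+", psi0 = 0.5,
                  up = c(1000, 1100), alt = c(1500, 1600),
                  dn = c(2000, 2100)) {
  if (strand == "-") { tmp <- up; up <- dn; dn <- tmp }
  df <- data.frame(event_id = as.integer(id), gene_id = paste0("G", id),
                   chrom = chrom, strand = strand,
                   up_start = up[1], up_end = up[2], alt_start = alt[1],
                   alt_end = alt[2], down_start = dn[1], down_end = dn[2],
                   psi_ctl = paste(rep(psi0, 5), collapse = ","),
                   psi_kd = paste(rep(psi0, 5), collapse = ","),
                   ijc_ctl = "30,30,30,30,30", sjc_ctl = "30,30,30,30,30",
                   ijc_kd = "30,30,30,30,30", sjc_kd = "30,30,30,30,30",
                   psi_ctl_mean = psi0, psi_kd_mean = psi0, dpsi = 0,
                   pvalue = 0.5, fdr = 0.5, stringsAsFactors = FALSE)
  class(df) <- c("ce_events", "data.frame")
  df
}

test_that("splice-site anchors are strand-aware and ordered", {
  ev <- mk_ev(1)
  an <- splice_site_anchors(ev)
  expect_identical(nrow(an), 6L)
  expect_identical(an$pos[an$anchor == "up_3ss"], 1000L)
  expect_identical(an$pos[an$anchor == "up_5ss"], 1100L)
  expect_identical(an$pos[an$anchor == "alt_3ss"], 1500L)
  expect_identical(an$pos[an$anchor == "down_5ss"], 2100L)
  anm <- splice_site_anchors(mk_ev(1, strand = "-"))
  expect_identical(anm$pos[anm$anchor == "up_3ss"], 2100L)
  expect_identical(anm$pos[anm$anchor == "up_5ss"], 2000L)
  expect_identical(anm$pos[anm$anchor == "alt_5ss"], 1500L)
})

test_that("occupancy profiles match a per-event brute-force tally", {
  # empty track: all fractions zero
  ev3 <- rbind(mk_ev(1), mk_ev(2, alt = c(1400, 1700)), mk_ev(3, strand = "-"))
  class(ev3) <- c("ce_events", "data.frame")
  p0 <- occupancy_profile(ev3, crosslink_track())
  expect_true(all(p0$fraction == 0))
  # a crosslink at genomic 1500 (+) sits at offset 0 of event 1's alt_3ss
  # only (event 2's alt exon starts at 1400, event 3 is on the minus strand)
  tr <- crosslink_track(c("chrT", "chrT"), c(1500L, 1500L), c("+", "-"),
                        c(2, 1))
  p1 <- occupancy_profile(ev3, tr)
  expect_equal(p1$fraction[p1$anchor == "alt_3ss" & p1$offset == 0], 1 / 3)
  # the minus-strand event sees genomic 1500 at offset 0 of its alt_5ss
  expect_equal(p1$fraction[p1$anchor == "alt_5ss" & p1$offset == 0], 1 / 3)
  # random oracle
  set.seed(6)
  pos <- sample(800:2400, 300)
  tr2 <- crosslink_track(rep("chrT", 600), c(pos, pos),
                         rep(c("+", "-"), each = 300),
                         rep(1L, 600))
  prof <- occupancy_profile(ev3, tr2)
  an <- splice_site_anchors(ev3)
  for (a in unique(an$anchor)) for (off in sample(-100:100, 12)) {
    hits <- vapply(seq_len(nrow(ev3)), function(i) {
      anc <- an[an$anchor == a & an$event_id == ev3$event_id[i], ]
      g <- if (anc$strand == "+") anc$pos + off else anc$pos - off
      any(tr2$pos == g & tr2$strand == anc$strand & tr2$chrom == anc$chrom)
    }, NA)
    expect_identical(
      prof$fraction[prof$anchor == a & prof$offset == off], mean(hits))
  }
})

test_that("PSI-matched sampling matches means and is seed-stable", {
  set.seed(10)
  reg <- stats::rbeta(200, 9, 1)           # concentrated near 0.9
  pool <- stats::runif(5000)               # uniform pool
  idx <- psi_matched_sample(reg, pool, seed = 1)
  expect_identical(length(idx), 200L)
  expect_lt(abs(mean(pool[idx]) - mean(reg)), 0.02)
  expect_identical(idx, psi_matched_sample(reg, pool, seed = 1))
  expect_false(identical(idx, psi_matched_sample(reg, pool, seed = 2)))
  # pool = regulated set itself: a permutation, identical mean
  perm <- psi_matched_sample(reg, reg, seed = 3)
  expect_identical(sort(perm), 1:200)
  # matching property across seeds
  for (s in 4:8) {
    i2 <- psi_matched_sample(reg, pool, seed = s)
    expect_lt(abs(mean(pool[i2]) - mean(reg)), 0.02)
  }
})

test_that("z-scores on a micro-instance equal a spreadsheet recomputation", {
  # 3 regulated events, 2-nt half-window, tiny pool, n_iter=4
  reg <- do.call(rbind, lapply(1:3, function(i)
    mk_ev(i, up = c(1000, 1100) + i * 2000, alt = c(1500, 1600) + i * 2000,
          dn = c(2000, 2100) + i * 2000)))
  pool <- do.call(rbind, lapply(4:9, function(i)
    mk_ev(i, up = c(1000, 1100) + i * 2000, alt = c(1500, 1600) + i * 2000,
          dn = c(2000, 2100) + i * 2000, psi0 = 0.4 + 0.02 * i)))
  class(reg) <- class(pool) <- c("ce_events", "data.frame")
  set.seed(99)
  pos <- sample(1000:20000, 2000)
  tr <- crosslink_track(rep("chrT", 2000), pos, rep("+", 2000),
                        sample(1:3, 2000, replace = TRUE))
  sets <- structure(list(down = reg, up = reg[0, ], unchanged = pool),
                    class = "regulated_sets")
  w <- 2; n_iter <- 4
  sm <- suppressWarnings(build_splicing_map(sets, tr, n_iter = n_iter,
                                            seed = 5, window = w,
                                            n_bins = 2))
  # manual recomputation
  ind <- clipmap:::event_anchor_indicators(reg, tr, w)
  f_obs <- unlist(lapply(clipmap:::anchor_names, function(a) colMeans(ind[[a]])))
  pool_ind <- clipmap:::event_anchor_indicators(pool, tr, w)
  bg <- t(vapply(seq_len(n_iter), function(it) {
    idx <- suppressWarnings(psi_matched_sample(
      reg$psi_ctl_mean, pool$psi_ctl_mean, 2,
      seed = clipmap:::substream_seed(5, it, "bg_down")))
    unlist(lapply(clipmap:::anchor_names, function(a)
      colMeans(pool_ind[[a]][idx, , drop = FALSE])))
  }, numeric(6 * (2 * w + 1))))
  mu <- colMeans(bg); sd <- apply(bg, 2, stats::sd)
  z_manual <- ifelse(sd == 0, 0, (f_obs - mu) / sd)
  expect_equal(sm$z[sm$set == "down"], unname(z_manual), tolerance = 1e-12)
  expect_equal(sm$f_obs[sm$set == "down"], unname(f_obs), tolerance = 1e-12)
  # BH adjustment agrees with a hand-rolled step-up procedure
  p <- sm$p[sm$set == "down"]
  m <- length(p)
  ord <- order(p)
  stepup <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    stepup[ord[i]] <- prev
  }
  expect_equal(sm$padj[sm$set == "down"], stepup, tolerance = 1e-12)
  # sd-zero positions are flagged with z = 0, p = 1
  expect_true(all(sm$z[sm$sd_zero] == 0 & sm$p[sm$sd_zero] == 1))
})

test_that("null regulated sets stay at the nominal significance rate", {
  st <- default_study()
  sets <- filter_significant_events(st$ce)
  pool <- sets$unchanged
  set.seed(77)
  fake_idx <- sample(nrow(pool), 30)
  fake <- structure(list(down = pool[fake_idx, ],
                         up = pool[0, ],
                         unchanged = pool[-fake_idx, ]),
                    class = "regulated_sets")
  sm <- suppressWarnings(build_splicing_map(fake, st$tracks$merged,
                                            n_iter = 50, seed = 3))
  rate <- mean(sm$significant)
  n_pos <- sum(sm$set == "down")
  expect_lte(rate, 0.05 + 2 * sqrt(0.05 * 0.95 / n_pos))
})

test_that("planted regulation shapes the splicing map as expected", {
  st <- default_study()
  sets <- filter_significant_events(st$ce)
  sm <- suppressWarnings(build_splicing_map(sets, st$tracks$merged,
                                            n_iter = 50, seed = 1))
  body_down <- sm$set == "down" &
    ((sm$anchor == "alt_3ss" & sm$offset >= 0 & sm$offset <= 50) |
       (sm$anchor == "alt_5ss" & sm$offset >= -50 & sm$offset <= 0))
  expect_gte(mean(sm$significant[body_down]), 0.8)
  flank_up <- sm$set == "up" &
    ((sm$anchor == "up_5ss" & sm$offset >= -50 & sm$offset <= 0) |
       (sm$anchor == "down_3ss" & sm$offset >= 0 & sm$offset <= 50))
  body_up <- sm$set == "up" &
    ((sm$anchor == "alt_3ss" & sm$offset >= 0 & sm$offset <= 50) |
       (sm$anchor == "alt_5ss" & sm$offset >= -50 & sm$offset <= 0))
  expect_gt(mean(sm$significant[flank_up]), mean(sm$significant[body_up]))
  expect_gte(mean(sm$significant[flank_up]), 0.5)
  # background PSI matching within 0.02 per iteration (matched means)
  for (set_name in c("down", "up")) {
    ev <- sets[[set_name]]
    for (it in 1:5) {
      idx <- suppressWarnings(psi_matched_sample(
        ev$psi_ctl_mean, sets$unchanged$psi_ctl_mean,
        seed = clipmap:::substream_seed(1, it, paste0("bg_", set_name))))
      expect_lt(abs(mean(sets$unchanged$psi_ctl_mean[idx]) -
                      mean(ev$psi_ctl_mean)), 0.02)
    }
  }
  # seed determinism of the whole map
  sm2 <- suppressWarnings(build_splicing_map(sets, st$tracks$merged,
                                             n_iter = 50, seed = 1))
  expect_identical(sm, sm2)
})

test_that("exon crosslink density follows the formula and tracks inclusion", {
  tr <- crosslink_track()
  ex <- data.frame(chrom = "chrT", start = 1L, end = 100L, strand = "+")
  expect_identical(exon_crosslink_density(ex, tr), log2(1 / 100))
  tr2 <- crosslink_track("chrT", 50L, "+", 7L)
  expect_identical(exon_crosslink_density(ex, tr2), log2(8 / 100))
  # synthetic study: median density increases across control-PSI bins
  st <- default_study()
  ce <- st$ce
  exons <- data.frame(chrom = ce$chrom, start = ce$alt_start,
                      end = ce$alt_end, strand = ce$strand)
  dens <- exon_crosslink_density(exons, st$tracks$merged)
  bins <- cut(ce$psi_ctl_mean, stats::quantile(ce$psi_ctl_mean,
                                               seq(0, 1, 0.2)),
              include.lowest = TRUE)
  med <- tapply(dens, bins, stats::median)
  expect_true(all(diff(med) > 0))
})
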