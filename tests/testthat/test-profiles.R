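test_that("a constant track yields an identically constant profile in every band", {
  fx <- make_profile_fixture(rep(1, 9))
  psi <- stats::setNames(c(10, 10, 10, 50, 50, 50, 90, 90, 90), fx$events$event_id)
  prof <- aggregate_profile(fx$events, fx$track, psi, flank = 300)
  expect_true(all(prof$mean_signal == 1))
  expect_setequal(unique(prof$psi_class), c("low", "mid", "high"))
  expect_setequal(unique(prof$boundary),
                  c("acceptor_intron", "acceptor_exon", "donor_exon", "donor_intron"))
})

test_that("the profile of a single event equals its extracted window", {
  bundle <- tiny_bundle()
  ev <- bundle$events[1, , drop = FALSE]
  tr <- bundle$tracks$actmark
  psi <- stats::setNames(95, ev$event_id)
  # the low and mid bands are empty here and produce omission warnings
  prof <- suppressWarnings(aggregate_profile(ev, tr, psi, flank = 80))
  acc <- prof[prof$site == "acceptor", ]
  expect_equal(acc$mean_signal,
               track_window(tr, ev$chrom, ev$acceptor_pos, 80, ev$strand))
  expect_equal(acc$position, seq(-80, 79))
})

test_that("the metagene profile equals the mean of per-event windows", {
  bundle <- tiny_bundle()
  ev <- bundle$events
  tr <- bundle$tracks$actmark
  psi <- stats::setNames(ifelse(ev$label == 1, 90, 10), ev$event_id)
  prof <- suppressWarnings(aggregate_profile(ev, tr, psi, flank = 60))
  for (band in c("low", "high")) {
    sel <- which((band == "high") == (ev$label == 1))
    oracle <- rowMeans(vapply(sel, function(i) {
      track_window(tr, ev$chrom[i], ev$donor_pos[i], 60, ev$strand[i])
    }, numeric(120)))
    got <- prof[prof$site == "donor" & prof$psi_class == band, "mean_signal"]
    expect_equal(got, oracle, tolerance = 1e-12)
  }
})

test_that("segment comparisons match the exhaustive-permutation oracle", {
  # segment means per event are exactly the constructed constants
  fx <- make_profile_fixture(c(1, 2, 3, 10, 11, 12))
  psi <- stats::setNames(c(10, 10, 10, 90, 90, 90), fx$events$event_id)
  cmp <- compare_segments(fx$events, fx$track, psi)
  lowhigh <- cmp[cmp$group1 == "low" & cmp$group2 == "high", ]
  expect_equal(nrow(lowhigh), 4)  # one row per segment
  # U = 0 and exact two-sided p = 0.1 for {1,2,3} vs {10,11,12}
  expect_true(all(lowhigh$statistic == 0))
  expect_true(all(abs(lowhigh$p_value - 0.1) < 1e-12))
  expect_true(all(lowhigh$stars == "ns"))
  expect_equal(oracle_ranksum_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
})

test_that("rank-sum p-values agree with enumeration across random small samples", {
  withr::with_seed(41, {
    for (i in 1:12) {
      nx <- sample(3:6, 1); ny <- sample(3:6, 1)
      x <- round(runif(nx) * 100)
      y <- round(runif(ny) * 100 + 30)
      if (anyDuplicated(c(x, y))) next  # exact path requires tie-free data
      wt <- stats::wilcox.test(x, y, exact = TRUE)
      expect_equal(wt$p.value, oracle_ranksum_p(x, y), tolerance = 1e-12)
    }
  })
})

test_that("a class-dependent shift concentrates significance in the shifted segment", {
  withr::with_seed(55, {
    n <- 40
    base <- make_profile_fixture(rep(0, n))
    psi <- stats::setNames(rep(c(10, 90), each = n / 2), base$events$event_id)
    v <- base$track$values$chr
    for (i in seq_len(n)) {
      s0 <- base$events$acceptor_pos[i]
      # noise everywhere in the tested span
      v[(s0 - 100 + 1):(s0 + 100)] <- rnorm(200, 0, 0.3)
      # included events additionally shifted inside segment C = [-50, 0)
      if (psi[i] > 50) {
        v[(s0 - 50 + 1):s0] <- v[(s0 - 50 + 1):s0] + 2
      }
    }
    tr <- signal_track("t", list(chr = v))
    cmp <- compare_segments(base$events, tr, psi)
    lh <- cmp[cmp$group1 == "low" & cmp$group2 == "high", ]
    expect_lt(lh$p_value[lh$segment == "C"], lh$p_value[lh$segment == "A"])
    expect_equal(lh$stars[lh$segment == "C"], "****")
  })
})

test_that("stars bins follow the published thresholds", {
  expect_equal(stars_from_p(c(0.5, 0.05, 0.011, 0.01, 0.001, 1e-4, 1e-5)),
               c("ns", "*", "*", "**", "***", "****", "****"))
})

test_that("expression-enrichment correlation recovers exact and null cases", {
  x <- 1:50
  expect_equal(correlate_expression_enrichment(x, 2 * x)$pcc, 1)
  withr::with_seed(61, {
    n <- 2000
    r <- correlate_expression_enrichment(runif(n), runif(n))
    expect_lt(abs(r$pcc), 3 / sqrt(n))
  })
  z <- correlate_expression_enrichment(rep(1, 10), rnorm(10))
  expect_true(is.na(z$pcc))
  expect_match(z$reason, "zero variance")
})

test_that("a positive signal-expression coupling yields a positive correlation", {
  withr::with_seed(62, {
    fpkm <- rexp(300, 1 / 10)
    signal <- 0.05 * fpkm + rnorm(300, 0, 0.2)
    r <- correlate_expression_enrichment(fpkm, signal)
    expect_gt(r$pcc, 0.4)
    expect_equal(nrow(r$groups), 3)
    # top tertile carries more signal than bottom tertile
    expect_gt(r$groups$mean_signal[3], r$groups$mean_signal[1])
  })
})

test_that("RBP binning places a peak 250 bp into the upstream intron in bin [-300,-200)", {
  ev <- data.frame(event_id = "e1", exon_id = "e1", chrom = "chr",
                   start = 5000, end = 5200, strand = "+", exon_length = 200,
                   acceptor_pos = 5000, donor_pos = 5200)
  peaks <- data.frame(chrom = "chr", start = 5000 - 250 - 20,
                      end = 5000 - 250 + 20, name = "SRSF1", score = 1000)
  prof <- bin_rbp_peaks(peaks, ev)
  acc <- prof[prof$site == "acceptor", ]
  expect_equal(acc$count[acc$bin_start == -300], 1)
  expect_equal(sum(acc$count), 1)
  expect_equal(acc$frequency[acc$bin_start == -300], 0.01)
})

test_that("peaks below the score filter are excluded entirely", {
  ev <- data.frame(event_id = "e1", exon_id = "e1", chrom = "chr",
                   start = 5000, end = 5200, strand = "+", exon_length = 200,
                   acceptor_pos = 5000, donor_pos = 5200)
  peaks <- data.frame(chrom = "chr", start = 4700, end = 4800,
                      name = "SRSF1", score = 999)
  prof <- bin_rbp_peaks(peaks, ev)
  expect_true(all(prof$count == 0))
  empty <- bin_rbp_peaks(peaks[0, ], ev)
  expect_true(all(empty$count == 0))
})

test_that("RBP profiles are order-invariant and mirror under strand flip", {
  withr::with_seed(71, {
    ev <- data.frame(event_id = c("e1", "e2"), exon_id = c("e1", "e2"),
                     chrom = "chr", start = c(5000, 9000), end = c(5200, 9150),
                     strand = "+", exon_length = c(200, 150),
                     acceptor_pos = c(5000, 9000), donor_pos = c(5200, 9150))
    peaks <- data.frame(chrom = "chr",
                        start = sort(sample(4000:10000, 40)),
                        end = 0, name = "X", score = 1000)
    peaks$end <- peaks$start + 30
    p1 <- bin_rbp_peaks(peaks, ev)
    p2 <- bin_rbp_peaks(peaks[rev(seq_len(nrow(peaks))), ], ev)
    expect_equal(p1, p2)
    # flip the strand of every event: offsets negate, so counts mirror
    ev_flip <- ev
    ev_flip$strand <- "-"
    ev_flip$acceptor_pos <- ev$end; ev_flip$donor_pos <- ev$start
    p3 <- bin_rbp_peaks(peaks, ev_flip)
    # compare the acceptor profile of the flipped events (anchored at the
    # other exon boundary) against a direct per-peak oracle
    mids <- floor((peaks$start + peaks$end) / 2)
    for (b in p3$bin_start[p3$site == "acceptor"]) {
      oracle <- sum(vapply(ev_flip$acceptor_pos, function(pos) {
        d <- pos - 1 - mids
        sum(d >= b & d < b + 100)
      }, numeric(1)))
      expect_equal(p3$count[p3$site == "acceptor" & p3$bin_start == b], oracle)
    }
  })
})

test_that("synthetic factor placement produces the expected single hot bin", {
  # splice sites spaced > 2 kb apart so each peak can hit only its own site
  cfg <- synthetic_config(n_genes = 20, exon_len = c(300, 400),
                          intron_len = c(1500, 1800), intergenic = c(1600, 2000),
                          channels = list(channel_spec("n1", "noise")), seed = 13)
  bundle <- generate_genome_and_annotation(cfg)
  peaks <- generate_rbp_peaks(bundle, factor_offsets = c(FAC = -250),
                              decoy_names = character(0))
  prof <- bin_rbp_peaks(peaks, bundle$events)
  acc <- prof[prof$site == "acceptor", ]
  expect_equal(acc$count[acc$bin_start == -300], nrow(bundle$events))
  expect_equal(sum(acc$count), nrow(bundle$events))
})
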