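test_that("one-hot encoding follows the A,C,G,T convention with all-zero N rows", {
  m <- one_hot("ACGT")
  expect_equal(unname(m), diag(4), ignore_attr = TRUE)
  expect_equal(unname(one_hot("N")), matrix(0, 1, 4))
  expect_equal(unname(one_hot("acgt")), diag(4), ignore_attr = TRUE)
  withr::with_seed(1, {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 50, replace = TRUE), collapse = "")
    m <- one_hot(s)
    chars <- strsplit(s, "")[[1]]
    for (i in 1:50) {
      expected <- as.numeric(c("A", "C", "G", "T") == chars[i])
      expect_equal(unname(m[i, ]), expected)
    }
  })
})

test_that("Poisson enrichment matches the closed-form upper tail and caps at 2", {
  expect_equal(poisson_enrichment(0, 1), 0)
  # P(X >= 5 | lambda = 1) = 0.003659847; -log10 = 2.4365 -> capped at 2
  expect_equal(poisson_enrichment(5, 1), 2)
  expect_equal(-log10(sum(dpois(5:50, 1))), 2.4365, tolerance = 1e-4)
  expect_equal(poisson_enrichment(1, 1), -log10(1 - exp(-1)), tolerance = 1e-12)
  expect_equal(poisson_enrichment(1, 1), 0.1992, tolerance = 1e-4)
  expect_error(poisson_enrichment(1, 0), "positive")
})

test_that("Poisson enrichment is monotone non-decreasing in the observed count", {
  vals <- poisson_enrichment(0:30, 3.7)
  expect_true(all(diff(vals) >= 0))
})

test_that("scale01 clips then rescales", {
  expect_equal(scale01(c(0, 1, 2), 2), c(0, 0.5, 1))
  expect_equal(scale01(5, 2), 1)
  withr::with_seed(2, {
    x <- rnorm(100, 1, 2); cap <- 1.7
    oracle <- vapply(x, function(v) min(max(v, 0), cap) / cap, numeric(1))
    expect_equal(scale01(x, cap), oracle)
  })
})

test_that("window extraction is strand-aware and mirror-symmetric", {
  L <- 400
  tr <- signal_track("t", list(chr = as.numeric(1:L)))
  w_plus <- track_window(tr, "chr", 200, 50, "+")
  w_minus <- track_window(tr, "chr", 200, 50, "-")
  expect_equal(length(w_plus), 100)
  expect_equal(w_minus, rev(w_plus))
  const <- signal_track("c", list(chr = rep(1, L)))
  expect_equal(track_window(const, "chr", 200, 50, "+"), rep(1, 100))
})

test_that("a bump 50 bp downstream of the site peaks at index flank+50 on both strands", {
  L <- 1000; flank <- 100; pos <- 500
  for (strand in c("+", "-")) {
    v <- rep(0, L)
    center0 <- if (strand == "+") pos + 50 else pos - 1 - 50
    g <- (center0 - 20):(center0 + 20)
    v[g + 1] <- exp(-((g - center0)^2) / 50)
    tr <- signal_track("b", list(chr = v))
    w <- track_window(tr, "chr", pos, flank, strand)
    expect_equal(which.max(w), flank + 50 + 1)
  }
})

test_that("out-of-bounds windows are padded with the fill value and N bases", {
  tr <- signal_track("t", list(chr = rep(2, 50)), fill = -1)
  w <- track_window(tr, "chr", 10, 20, "+")
  expect_equal(w, c(rep(-1, 10), rep(2, 30)))
  genome <- Biostrings::DNAStringSet(c(chr = strrep("A", 50)))
  s <- dna_window(genome, "chr", 10, 20, "+")
  expect_equal(s, paste0(strrep("N", 10), strrep("A", 30)))
})

test_that("reverse_time is an involution that flips ramps and preserves constants", {
  w <- cbind(one_hot("ACGTACGTAC"), ramp = 1:10, const = rep(2, 10))
  r1 <- reverse_time(w, "ramp")
  expect_equal(r1[, "ramp"], rev(1:10), ignore_attr = TRUE)
  expect_equal(r1[, "const"], w[, "const"])
  expect_equal(r1[, "A"], w[, "A"])  # DNA untouched by default channel subset
  expect_equal(reverse_time(r1, "ramp"), w)
  r2 <- reverse_time(w, "const")
  expect_equal(r2[, "const"], w[, "const"])
  expect_error(reverse_time(w, "nope"), "unknown channels")
})

test_that("orientation invariant: acceptor windows read intron then exon, donors exon then intron", {
  # genome where exons are all-A and introns/intergenic all-C
  flank <- 20
  for (strand in c("+", "-")) {
    L <- 600
    chars <- rep("C", L)
    s0 <- 300L; e0 <- 400L           # one exon [300, 400) 0-based
    chars[(s0 + 1):e0] <- "A"
    genome <- Biostrings::DNAStringSet(stats::setNames(paste(chars, collapse = ""), "chr"))
    acc_pos <- if (strand == "+") s0 else e0
    don_pos <- if (strand == "+") e0 else s0
    acc <- dna_window(genome, "chr", acc_pos, flank, strand)
    don <- dna_window(genome, "chr", don_pos, flank, strand)
    base_at <- function(w, i) substr(w, i, i)
    # complement of C is G on the minus strand; exonic A complements to T
    intron_base <- if (strand == "+") "C" else "G"
    exon_base <- if (strand == "+") "A" else "T"
    expect_equal(base_at(acc, 1), intron_base)
    expect_equal(base_at(acc, 2 * flank), exon_base)
    expect_equal(base_at(don, 1), exon_base)
    expect_equal(base_at(don, 2 * flank), intron_base)
  }
})

test_that("strand symmetry: reverse-complementing the genome and flipping strands preserves windows", {
  bundle <- tiny_bundle()
  ev <- bundle$events
  flank <- 30
  genome_rc <- Biostrings::reverseComplement(bundle$genome)
  lens <- Biostrings::width(bundle$genome)
  names(lens) <- names(bundle$genome)
  for (i in seq_len(min(nrow(ev), 10))) {
    L <- lens[[ev$chrom[i]]]
    flip <- function(pos) L - pos
    new_strand <- if (ev$strand[i] == "+") "-" else "+"
    w1 <- dna_window(bundle$genome, ev$chrom[i], ev$acceptor_pos[i], flank, ev$strand[i])
    w2 <- dna_window(genome_rc, ev$chrom[i], flip(ev$acceptor_pos[i]), flank, new_strand)
    expect_equal(w2, w1)
  }
})

test_that("build_dataset produces the documented shapes and channel registries", {
  bundle <- tiny_bundle()
  ds <- make_model_dataset(bundle, flank = 50)
  n <- nrow(bundle$events)
  expect_s3_class(ds, "splice_dataset")
  expect_equal(dim(ds$acceptor), c(n, 100, 4 + length(bundle$tracks)))
  expect_equal(dim(ds$donor), dim(ds$acceptor))
  expect_equal(ds$channel_names[1:4], c("A", "C", "G", "T"))
  expect_true(all(ds$acceptor >= 0 & ds$acceptor <= 1))
  expect_true(all(ds$donor >= 0 & ds$donor <= 1))
  dna <- ds$acceptor[, , 1:4]
  expect_true(all(dna %in% c(0, 1)))
  # each DNA position has at most one hot channel
  expect_true(all(apply(dna, c(1, 2), sum) <= 1))
  # DNA-only dataset has exactly 4 channels
  dna_only <- subset_channels(ds, character(0))
  expect_equal(dim(dna_only$acceptor)[3], 4)
  expect_equal(dna_only$channel_names, c("A", "C", "G", "T"))
})

test_that("events on missing contigs are dropped with a message", {
  bundle <- tiny_bundle()
  ev <- bundle$events
  ev$chrom[1] <- "chrMissing"
  expect_message(
    ds <- build_dataset(ev, bundle$genome, bundle$tracks, flank = 30),
    "dropping 1 event")
  expect_equal(length(ds$event_id), nrow(ev) - 1)
})

test_that("bedGraph round trip reproduces in-memory track windows", {
  bundle <- tiny_bundle()
  dir <- withr::local_tempdir()
  write_synthetic_data(bundle, dir)
  tr_mem <- bundle$tracks[[1]]
  tr_file <- read_signal_track(file.path(dir, paste0(tr_mem$name, ".bedGraph")))
  ev <- bundle$events[1:5, ]
  for (i in seq_len(nrow(ev))) {
    w_mem <- track_window(tr_mem, ev$chrom[i], ev$acceptor_pos[i], 40, ev$strand[i])
    w_file <- track_window(tr_file, ev$chrom[i], ev$acceptor_pos[i], 40, ev$strand[i])
    # values on disk are rounded to 4 decimals
    expect_lt(max(abs(w_file - w_mem)), 5.1e-5)
  }
})
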