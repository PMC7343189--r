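# Fixtures are generated in code and cached for the duration of the test run.

.fixture_env <- new.env(parent = emptyenv())

get_fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_env)) {
    assign(name, build(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env)
}

tiny_bundle <- function() get_fixture("tiny_bundle", function() {
  simulate_splicing_data("tiny", seed = 11)
})

tiny_dataset <- function() get_fixture("tiny_dataset", function() {
  make_model_dataset(tiny_bundle(), flank = 50)
})

strong_bundle <- function() get_fixture("strong_bundle", function() {
  simulate_splicing_data("strong-signal", seed = 101)
})

strong_dataset <- function() get_fixture("strong_dataset", function() {
  make_model_dataset(strong_bundle(), flank = 100)
})

# a small GTF written from code: 3 genes x 4 exons on two strands, plus one
# duplicated exon shared between two transcripts of the same gene
write_toy_gtf <- function(path) {
  line <- function(chrom, s, e, strand, gid, tid, num, gtype = "protein_coding") {
    sprintf(paste0("%s\ttoy\texon\t%d\t%d\t.\t%s\t.\t",
                   "gene_id \"%s\"; transcript_id \"%s\"; exon_number %d; gene_type \"%s\";"),
            chrom, s, e, strand, gid, tid, num, gtype)
  }
  lines <- c(
    line("chr1", 101, 200, "+", "g1", "g1.t1", 1),
    line("chr1", 301, 380, "+", "g1", "g1.t1", 2),
    line("chr1", 501, 600, "+", "g1", "g1.t1", 3),
    line("chr1", 801, 900, "+", "g1", "g1.t1", 4),
    # second isoform sharing exon 2 of g1
    line("chr1", 101, 200, "+", "g1", "g1.t2", 1),
    line("chr1", 301, 380, "+", "g1", "g1.t2", 2),
    line("chr1", 801, 900, "+", "g1", "g1.t2", 3),
    line("chr1", 2001, 2100, "-", "g2", "g2.t1", 4),
    line("chr1", 2301, 2400, "-", "g2", "g2.t1", 3),
    line("chr1", 2601, 2700, "-", "g2", "g2.t1", 2),
    line("chr1", 2901, 3000, "-", "g2", "g2.t1", 1),
    line("chr2", 101, 220, "+", "g3", "g3.t1", 1),
    line("chr2", 401, 500, "+", "g3", "g3.t1", 2),
    line("chr2", 701, 790, "+", "g3", "g3.t1", 3),
    line("chr2", 901, 1000, "+", "g3", "g3.t1", 4))
  writeLines(lines, path)
  path
}

# constant-valued track over given chromosome lengths
constant_track <- function(value, chrom_lengths, name = "const") {
  signal_track(name, lapply(chrom_lengths, function(L) rep(value, L)))
}

# events laid out on one chromosome with easily controlled per-event signal
make_profile_fixture <- function(values_by_event, exon_len = 200, gap = 2000,
                                 flank_pad = 1200) {
  n <- length(values_by_event)
  starts <- flank_pad + (seq_len(n) - 1) * (exon_len + gap)
  ev <- data.frame(
    event_id = sprintf("ev%d", seq_len(n)), exon_id = sprintf("ev%d", seq_len(n)),
    chrom = "chr", start = starts, end = starts + exon_len, strand = "+",
    exon_length = exon_len, acceptor_pos = starts, donor_pos = starts + exon_len,
    stringsAsFactors = FALSE)
  L <- starts[n] + exon_len + flank_pad
  v <- rep(0, L)
  for (i in seq_len(n)) {
    # constant value across the whole neighbourhood of event i
    lo <- starts[i] - flank_pad + 1
    hi <- starts[i] + exon_len + flank_pad
    v[lo:hi] <- values_by_event[i]
  }
  list(events = ev, track = signal_track("t", list(chr = v)))
}
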