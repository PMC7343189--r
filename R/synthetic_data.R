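#' Specification of one synthetic signal channel
#'
#' Channels emulate epigenomic tracks with class-coupled signal around splice
#' sites. `bump` adds a Gaussian of half-width `width` centred `offset` bp
#' from the named splice site (offsets in transcription direction: positive =
#' downstream of the boundary); `ramp` adds a monotone 5'-to-3' gradient
#' `amp * (0.5 + asymmetry * d / (2 * width))` over `|d| <= width` for
#' included events, mirrored (slope negated) for skipped events, so temporal
#' direction itself is class-informative; at `asymmetry = 0` both classes
#' degenerate to a symmetric plateau; `noise` adds no
#' deterministic signal. All kinds add white noise with SD `noise_sd` and
#' the final track is clipped at zero. Bumps may also be skewed 5'-to-3' via
#' `asymmetry` (multiplicative `1 + asymmetry * tanh(d / width)` factor).
#'
#' @param name channel name.
#' @param kind `"bump"`, `"ramp"` or `"noise"`.
#' @param anchors named numeric vector of offsets, names in
#'   `{acceptor, donor}` (e.g. `c(acceptor = 100, donor = -50)`).
#' @param width bump SD / ramp half-span in bp.
#' @param amp_included,amp_skipped signal amplitude for included / skipped
#'   events (mid-PSI events get the average).
#' @param noise_sd white-noise SD.
#' @param asymmetry 5'-to-3' skew in `[-1, 1]`.
#' @return list of class `channel_spec`.
#' @export
channel_spec <- function(name, kind = c("bump", "ramp", "noise"),
                         anchors = c(acceptor = 0), width = 60,
                         amp_included = 1, amp_skipped = 0,
                         noise_sd = 0.1, asymmetry = 0) {
  kind <- match.arg(kind)
  stopifnot(width > 0, amp_included >= 0, amp_skipped >= 0,
            abs(asymmetry) <= 1,
            all(names(anchors) %in% c("acceptor", "donor")))
  structure(list(name = name, kind = kind, anchors = anchors, width = width,
                 amp_included = amp_included, amp_skipped = amp_skipped,
                 noise_sd = noise_sd, asymmetry = asymmetry),
            class = "channel_spec")
}

#' Default synthetic channel roster
#'
#' Six channels mimicking, by role only, a core epigenomic set: an activating
#' mark enriched on included exons ("actmark", bumps 100 bp into the exon at
#' the acceptor and 50 bp into the exon at the donor), a repressive mark
#' enriched on skipped exons ("repmark"), an accessibility channel with a
#' milder positive association ("access"), and three pure-noise channels.
#' The names are placeholders, not biological claims.
#'
#' @return list of [channel_spec()] objects.
#' @export
default_channels <- function() {
  list(
    channel_spec("actmark", "bump", anchors = c(acceptor = 100, donor = -50),
                 width = 60, amp_included = 1, amp_skipped = 0, noise_sd = 0.1),
    channel_spec("repmark", "bump", anchors = c(acceptor = 0, donor = 0),
                 width = 80, amp_included = 0, amp_skipped = 0.6, noise_sd = 0.1),
    channel_spec("access", "bump", anchors = c(acceptor = -50),
                 width = 80, amp_included = 0.5, amp_skipped = 0.15, noise_sd = 0.1),
    channel_spec("noise1", "noise", noise_sd = 0.15),
    channel_spec("noise2", "noise", noise_sd = 0.15),
    channel_spec("noise3", "noise", noise_sd = 0.15)
  )
}

#' Synthetic-data configuration
#'
#' @param n_genes number of genes (one transcript each).
#' @param exons_per_gene inclusive range of exon counts per gene.
#' @param exon_len,intron_len,intergenic inclusive bp ranges.
#' @param p_included probability that a cassette exon is included.
#' @param p_mid fraction of events given mid-range PSI (40-60%).
#' @param channels list of [channel_spec()]s.
#' @param fragment_length sequencing fragment length `L_f` in bp.
#' @param read_depth mean junction reads per event.
#' @param canonical_fraction fraction of introns receiving canonical GT/AG
#'   dinucleotides at their boundaries.
#' @param n_chroms number of chromosomes to spread genes over.
#' @param seed master seed; sub-steps (tracks, reads, peaks) derive their own
#'   seeds from it, so each generator is independently reproducible.
#' @return list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_genes = 50, exons_per_gene = c(3, 6),
                             exon_len = c(80, 160), intron_len = c(200, 400),
                             intergenic = c(800, 1200),
                             p_included = 0.5, p_mid = 0,
                             channels = default_channels(),
                             fragment_length = 100, read_depth = 50,
                             canonical_fraction = 0.95, n_chroms = 2,
                             seed = 1) {
  stopifnot(n_genes >= 1, exons_per_gene[1] >= 2, p_included > 0, p_included < 1,
            p_mid >= 0, p_mid < 1, fragment_length > 0, read_depth >= 0,
            canonical_fraction >= 0, canonical_fraction <= 1)
  structure(as.list(environment()), class = "synthetic_config")
}

#' Named generator presets
#'
#' * `"strong-signal"`: ~2,000 cassette events, the 6-channel default roster,
#'   strong class-coupled signal (bump amplitude about 10x the noise SD);
#'   the end-to-end training benchmark.
#' * `"metagene"`: fewer genes with long introns and exons (500-600 bp, so
#'   the acceptor- and donor-anchored bumps are spatially resolvable), a
#'   fraction of mid-PSI events; sized for +/-500 bp metagene profiles.
#' * `"importance"`: a single class-informative bump channel plus three
#'   noise channels, so that leave-one-out ablation has an unambiguous
#'   ground-truth ranking (the default roster's three informative channels
#'   are mutually redundant, which by design nulls their ablation deltas).
#' * `"direction"`: one ramp channel whose 5'-to-3' slope is set by
#'   `asymmetry` plus two noise channels; used by the time-reversal test.
#'   Noise is deliberately higher so the classification margin is small
#'   enough for direction perturbations to register in F1.
#' * `"tiny"`: a dozen genes for fast unit tests.
#'
#' @param preset preset name.
#' @param seed master seed.
#' @param asymmetry ramp slope for the `"direction"` preset (0 = symmetric
#'   plateau).
#' @return a [synthetic_config()].
#' @export
preset_config <- function(preset = c("strong-signal", "importance", "metagene",
                                     "direction", "tiny"),
                          seed = 1, asymmetry = 0.8) {
  preset <- match.arg(preset)
  switch(preset,
    "strong-signal" = synthetic_config(n_genes = 800, seed = seed),
    "importance" = synthetic_config(
      n_genes = 400, seed = seed,
      channels = list(
        channel_spec("actmark", "bump", anchors = c(acceptor = 100, donor = -50),
                     width = 60, amp_included = 1, amp_skipped = 0, noise_sd = 0.1),
        channel_spec("noise1", "noise", noise_sd = 0.15),
        channel_spec("noise2", "noise", noise_sd = 0.15),
        channel_spec("noise3", "noise", noise_sd = 0.15))),
    "metagene" = synthetic_config(
      n_genes = 150, exon_len = c(500, 600), intron_len = c(1100, 1400),
      intergenic = c(1300, 1700), p_mid = 0.25, seed = seed),
    "direction" = synthetic_config(
      n_genes = 300, seed = seed,
      channels = list(
        channel_spec("dirsig", "ramp", anchors = c(acceptor = 0, donor = 0),
                     width = 60, amp_included = 1, amp_skipped = 0.6,
                     noise_sd = 0.2, asymmetry = asymmetry),
        channel_spec("noiseA", "noise", noise_sd = 0.15),
        channel_spec("noiseB", "noise", noise_sd = 0.15))),
    "tiny" = synthetic_config(n_genes = 12, seed = seed)
  )
}

runif_int <- function(n, range) {
  as.integer(range[1] + floor(stats::runif(n) * (range[2] - range[1] + 1)))
}

#' Generate a toy genome, gene annotation and event truth table
#'
#' Lays out multi-exon genes (one transcript each, random strand) across
#' chromosomes with random uniform base composition, writes canonical GT/AG
#' dinucleotides at a configurable fraction of intron boundaries
#' (strand-aware), assigns every internal exon a ground-truth class
#' (included / skipped / mid) and true PSI, and returns the corresponding
#' boundary coordinates.
#'
#' @param config a [synthetic_config()].
#' @return list of class `synthetic_bundle`: `genome` (`DNAStringSet`),
#'   `exons` (`GRanges` with GTF-style metadata), `events` (truth table with
#'   `event_id`, coordinates, `class`, `true_psi`, `label`), `config`.
#' @export
generate_genome_and_annotation <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  withr::with_seed(config$seed, {
    n <- config$n_genes
    chrom_of <- rep(seq_len(config$n_chroms), length.out = n)
    cursor <- rep(0L, config$n_chroms)
    exon_rows <- vector("list", n)
    intron_rows <- vector("list", n)
    for (g in seq_len(n)) {
      ch <- chrom_of[g]
      n_ex <- runif_int(1, config$exons_per_gene)
      ex_len <- runif_int(n_ex, config$exon_len)
      in_len <- if (n_ex > 1) runif_int(n_ex - 1, config$intron_len) else integer(0)
      gap <- runif_int(1, config$intergenic)
      gene_start0 <- cursor[ch] + gap
      starts0 <- gene_start0 + c(0L, cumsum(ex_len[-n_ex] + in_len))
      ends0 <- starts0 + ex_len
      cursor[ch] <- ends0[n_ex]
      strand <- sample(c("+", "-"), 1)
      gene_id <- sprintf("gene%04d", g)
      rank <- if (strand == "+") seq_len(n_ex) else rev(seq_len(n_ex))
      exon_rows[[g]] <- data.frame(
        chrom_i = ch, start0 = starts0, end0 = ends0, strand = strand,
        gene_id = gene_id, exon_id = sprintf("%s_e%d", gene_id, seq_len(n_ex)),
        rank = rank, genomic_index = seq_len(n_ex), n_ex = n_ex,
        stringsAsFactors = FALSE)
      if (n_ex > 1) {
        intron_rows[[g]] <- data.frame(chrom_i = ch, left0 = ends0[-n_ex],
                                       right0 = starts0[-1], strand = strand)
      }
    }
    exdf <- do.call(rbind, exon_rows)
    indf <- do.call(rbind, intron_rows)
    chrom_len <- cursor + runif_int(config$n_chroms, config$intergenic) + 1200L
    chrom_names <- sprintf("chrS%d", seq_len(config$n_chroms))

    seqs <- lapply(seq_len(config$n_chroms), function(ch) {
      s <- sample(c("A", "C", "G", "T"), chrom_len[ch], replace = TRUE)
      here <- indf[indf$chrom_i == ch, , drop = FALSE]
      if (nrow(here)) {
        canon <- stats::runif(nrow(here)) < config$canonical_fraction
        for (j in which(canon)) {
          l0 <- here$left0[j]; r0 <- here$right0[j]
          if (here$strand[j] == "+") {
            s[(l0 + 1):(l0 + 2)] <- c("G", "T")   # donor side GT
            s[(r0 - 1):r0] <- c("A", "G")         # acceptor side AG
          } else {
            s[(r0 - 1):r0] <- c("A", "C")         # revcomp GT
            s[(l0 + 1):(l0 + 2)] <- c("C", "T")   # revcomp AG
          }
        }
      }
      paste(s, collapse = "")
    })
    genome <- Biostrings::DNAStringSet(unlist(seqs))
    names(genome) <- chrom_names

    exdf$chrom <- chrom_names[exdf$chrom_i]
    internal <- exdf[exdf$genomic_index > 1 & exdf$genomic_index < exdf$n_ex, , drop = FALSE]
    n_ev <- nrow(internal)
    class <- sample(c("included", "skipped", "mid"), n_ev, replace = TRUE,
                    prob = c(config$p_included * (1 - config$p_mid),
                             (1 - config$p_included) * (1 - config$p_mid),
                             config$p_mid))
    true_psi <- ifelse(class == "included", stats::runif(n_ev, 0.85, 0.98),
                       ifelse(class == "skipped", stats::runif(n_ev, 0.02, 0.15),
                              stats::runif(n_ev, 0.40, 0.60)))
    plus <- internal$strand == "+"
    events <- data.frame(
      event_id = internal$exon_id, exon_id = internal$exon_id,
      gene_id = internal$gene_id, chrom = internal$chrom,
      start = internal$start0, end = internal$end0, strand = internal$strand,
      exon_length = internal$end0 - internal$start0,
      acceptor_pos = ifelse(plus, internal$start0, internal$end0),
      donor_pos = ifelse(plus, internal$end0, internal$start0),
      class = class, true_psi = true_psi,
      label = as.integer(ifelse(class == "mid", true_psi >= 0.5,
                                class == "included")),
      stringsAsFactors = FALSE)

    exons <- GenomicRanges::GRanges(
      seqnames = factor(exdf$chrom, levels = chrom_names),
      ranges = IRanges::IRanges(start = exdf$start0 + 1L, end = exdf$end0),
      strand = exdf$strand,
      seqlengths = stats::setNames(as.integer(chrom_len), chrom_names))
    exons$type <- "exon"
    exons$source <- "splicernn_synthetic"
    exons$gene_id <- exdf$gene_id
    exons$transcript_id <- paste0(exdf$gene_id, ".t1")
    exons$gene_type <- "protein_coding"
    exons$exon_id <- exdf$exon_id
    exons$exon_number <- exdf$rank
    exons$exon_rank <- exdf$rank

    structure(list(genome = genome, exons = exons, events = events,
                   config = config),
              class = "synthetic_bundle")
  })
}

# transcription-direction genomic centre of an anchor offset
anchor_center <- function(pos, strand, offset) {
  ifelse(strand == "+", pos + offset, pos - 1 - offset)
}

#' Generate class-coupled signal tracks for a synthetic bundle
#'
#' Per channel: white noise over every base plus, for each event and anchor,
#' a deterministic class-amplitude component (Gaussian bump or 5'-to-3'
#' ramp), strand-oriented; the final per-base vector is clipped at zero.
#' Uses seed `config$seed + 1`.
#'
#' @param bundle a `synthetic_bundle`.
#' @return named list of [signal_track()] objects.
#' @export
generate_tracks <- function(bundle) {
  config <- bundle$config
  events <- bundle$events
  chrom_len <- stats::setNames(GenomeInfoDb::seqlengths(bundle$exons),
                               names(bundle$genome))
  withr::with_seed(config$seed + 1L, {
    tracks <- lapply(config$channels, function(sp) {
      vecs <- lapply(chrom_len, function(L) {
        if (sp$noise_sd > 0) stats::rnorm(L, 0, sp$noise_sd) else numeric(L)
      })
      if (sp$kind != "noise") {
        amp_of <- c(included = sp$amp_included, skipped = sp$amp_skipped,
                    mid = (sp$amp_included + sp$amp_skipped) / 2)
        for (i in seq_len(nrow(events))) {
          amp <- amp_of[[events$class[i]]]
          if (amp == 0) next
          for (site in names(sp$anchors)) {
            pos <- events[[paste0(site, "_pos")]][i]
            ctr <- anchor_center(pos, events$strand[i], sp$anchors[[site]])
            half <- if (sp$kind == "bump") ceiling(4 * sp$width) else sp$width
            g <- max(0, ctr - half):min(chrom_len[[events$chrom[i]]] - 1, ctr + half)
            d <- if (events$strand[i] == "+") g - ctr else ctr - g
            add <- if (sp$kind == "bump") {
              amp * exp(-d^2 / (2 * sp$width^2)) * (1 + sp$asymmetry * tanh(d / sp$width))
            } else {
              # ramp slope runs 5'->3' for included events and is mirrored
              # for skipped ones, so temporal direction itself carries class
              # information when asymmetry > 0
              s_class <- if (events$class[i] == "skipped") -1 else 1
              amp * pmin(pmax(0.5 + s_class * sp$asymmetry * d / (2 * sp$width), 0), 1)
            }
            ch <- events$chrom[i]
            vecs[[ch]][g + 1] <- vecs[[ch]][g + 1] + add
          }
        }
      }
      vecs <- lapply(vecs, function(v) pmax(v, 0))
      signal_track(sp$name, vecs, fill = 0)
    })
    names(tracks) <- vapply(config$channels, `[[`, character(1), "name")
    tracks
  })
}

#' Simulate junction and exon read counts at known PSI
#'
#' Total junction reads per event are Poisson with mean `read_depth`;
#' inclusion reads are binomial with success probability
#' `p (L_i + L_f) / (p (L_i + L_f) + (1 - p) L_f)`, the length-biased
#' probability under which [compute_psi()] recovers the true inclusion
#' fraction `p` in expectation. Exon counts are Poisson with mean
#' `read_depth * p`. Uses seed `config$seed + 2`.
#'
#' @param bundle a `synthetic_bundle`.
#' @return list with `junctions` (`event_id`, `f_incl`, `f_excl`),
#'   `exon_counts` (`event_id`, `count`) and `fragment_length`.
#' @export
simulate_junction_reads <- function(bundle) {
  config <- bundle$config
  ev <- bundle$events
  withr::with_seed(config$seed + 2L, {
    n <- nrow(ev)
    total <- stats::rpois(n, config$read_depth)
    p <- ev$true_psi
    li <- ev$exon_length; lf <- config$fragment_length
    q <- p * (li + lf) / (p * (li + lf) + (1 - p) * lf)
    f_incl <- stats::rbinom(n, total, q)
    list(junctions = data.frame(event_id = ev$event_id, f_incl = f_incl,
                                f_excl = total - f_incl,
                                stringsAsFactors = FALSE),
         exon_counts = data.frame(event_id = ev$event_id,
                                  count = stats::rpois(n, config$read_depth * p),
                                  stringsAsFactors = FALSE),
         fragment_length = config$fragment_length)
  })
}

#' Generate synthetic RBP peaks around splice sites
#'
#' Places one fixed-offset peak per event and factor (score 1000) at the
#' requested splice site, plus uniformly scattered decoy-factor peaks.
#' Offsets are in transcription direction. Uses seed `config$seed + 3`.
#'
#' @param bundle a `synthetic_bundle`.
#' @param factor_offsets named numeric vector: peak midpoint offset per
#'   factor (default `c(SRSF1 = -250, HNRNPC = 50)`).
#' @param site splice site the factors anchor to (default `"acceptor"`).
#' @param width peak width in bp.
#' @param decoy_names factors placed uniformly at random.
#' @param n_decoy decoy peaks per decoy factor.
#' @param score peak score (default 1000, i.e. passing the score filter).
#' @return data frame: `chrom`, `start` (0-based), `end`, `name`, `score`,
#'   `strand`.
#' @export
generate_rbp_peaks <- function(bundle,
                               factor_offsets = c(SRSF1 = -250, HNRNPC = 50),
                               site = "acceptor", width = 40,
                               decoy_names = "DECOY1", n_decoy = 200,
                               score = 1000) {
  config <- bundle$config
  ev <- bundle$events
  chrom_len <- GenomeInfoDb::seqlengths(bundle$exons)
  withr::with_seed(config$seed + 3L, {
    rows <- list()
    for (f in names(factor_offsets)) {
      mid <- anchor_center(ev[[paste0(site, "_pos")]], ev$strand,
                           factor_offsets[[f]])
      rows[[f]] <- data.frame(chrom = ev$chrom,
                              start = mid - width %/% 2,
                              end = mid - width %/% 2 + width,
                              name = f, score = score, strand = ev$strand,
                              stringsAsFactors = FALSE)
    }
    for (f in decoy_names) {
      ch <- sample(names(chrom_len), n_decoy, replace = TRUE)
      mid <- floor(stats::runif(n_decoy) * (chrom_len[ch] - 2 * width)) + width
      rows[[paste0("decoy_", f)]] <- data.frame(
        chrom = ch, start = mid - width %/% 2,
        end = mid - width %/% 2 + width, name = f, score = score,
        strand = sample(c("+", "-"), n_decoy, replace = TRUE),
        stringsAsFactors = FALSE)
    }
    if (length(rows) == 0) {
      return(data.frame(chrom = character(0), start = integer(0),
                        end = integer(0), name = character(0),
                        score = numeric(0), strand = character(0)))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' One-call synthetic data simulation
#'
#' Runs [generate_genome_and_annotation()], [generate_tracks()] and
#' [simulate_junction_reads()] with the sub-seeds derived from
#' `config$seed`.
#'
#' @param config a [synthetic_config()] or preset name for
#'   [preset_config()].
#' @param seed seed used when `config` is a preset name.
#' @return `synthetic_bundle` extended with `tracks` and `reads`.
#' @export
simulate_splicing_data <- function(config = "strong-signal", seed = 1) {
  if (is.character(config)) config <- preset_config(config, seed = seed)
  bundle <- generate_genome_and_annotation(config)
  bundle$tracks <- generate_tracks(bundle)
  bundle$reads <- simulate_junction_reads(bundle)
  bundle
}

#' Build the model dataset for a simulated bundle
#'
#' @param bundle result of [simulate_splicing_data()].
#' @param flank half-window bp per splice site (default 100).
#' @return a labelled `splice_dataset` (labels = ground-truth class).
#' @export
make_model_dataset <- function(bundle, flank = 100) {
  build_dataset(bundle$events, bundle$genome, bundle$tracks, flank = flank,
                labels = stats::setNames(bundle$events$label, bundle$events$event_id))
}

#' Write a synthetic bundle to standard file formats
#'
#' FASTA genome, GTF annotation, one bedGraph per channel (values rounded to
#' 4 decimals), junction/exon-count TSVs, optional BED peaks and a JSON truth
#' table. Output is byte-deterministic given the config seed.
#'
#' @param bundle a bundle from [simulate_splicing_data()].
#' @param dir output directory (created if needed).
#' @param peaks optional peak table from [generate_rbp_peaks()].
#' @return invisibly, the directory.
#' @export
write_synthetic_data <- function(bundle, dir, peaks = NULL) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  Biostrings::writeXStringSet(bundle$genome, file.path(dir, "genome.fa"))
  rtracklayer::export(bundle$exons, file.path(dir, "annotation.gtf"), format = "gtf")
  for (tr in bundle$tracks) {
    rl <- methods::as(lapply(tr$values, function(v) S4Vectors::Rle(round(v, 4))),
                      "SimpleRleList")
    gr <- methods::as(rl, "GRanges")
    gr <- gr[gr$score != 0]
    rtracklayer::export(gr, file.path(dir, paste0(tr$name, ".bedGraph")),
                        format = "bedGraph")
  }
  write_tsv(bundle$reads$junctions, file.path(dir, "junctions.tsv"))
  write_tsv(bundle$reads$exon_counts, file.path(dir, "exon_counts.tsv"))
  if (!is.null(peaks)) {
    write_tsv(peaks, file.path(dir, "peaks.tsv"))
  }
  truth <- bundle$events
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA)
  invisible(dir)
}
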