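DNA_CHANNELS <- c("A", "C", "G", "T")

#' One-hot encode a DNA sequence
#'
#' Channel order A, C, G, T; `N` and any other ambiguity code yields an
#' all-zero row. Case-insensitive.
#'
#' @param dna_sequence single character string.
#' @return numeric matrix (nchar x 4) with column names `A,C,G,T`.
#' @export
one_hot <- function(dna_sequence) {
  chars <- strsplit(toupper(as.character(dna_sequence)), "", fixed = TRUE)[[1]]
  m <- matrix(0, length(chars), 4, dimnames = list(NULL, DNA_CHANNELS))
  idx <- match(chars, DNA_CHANNELS)
  ok <- which(!is.na(idx))
  m[cbind(ok, idx[ok])] <- 1
  m
}

#' Poisson upper-tail enrichment score
#'
#' `min(-log10 P(X >= obs | Poisson(rate)), cap)` -- the MACS-style
#' enrichment of an observed count over a local background rate, capped at
#' `cap = 2` (a p-value floor of 1e-2) to contain the dynamic range.
#'
#' @param obs_count non-negative integer count(s).
#' @param background_rate positive Poisson background rate.
#' @param cap upper cap on the -log10 p-value.
#' @return numeric vector of capped enrichment values.
#' @export
poisson_enrichment <- function(obs_count, background_rate, cap = 2) {
  if (any(background_rate <= 0)) stop("background_rate must be positive")
  if (any(obs_count < 0)) stop("obs_count must be non-negative")
  p <- stats::ppois(obs_count - 1, background_rate, lower.tail = FALSE)
  pmin(-log10(p), cap)
}

#' Clip-and-scale signal values to [0, 1]
#'
#' Values are clipped to `[0, cap]` and divided by `cap`.
#'
#' @param values numeric vector.
#' @param cap positive cap.
#' @return numeric vector in `[0, 1]`.
#' @export
scale01 <- function(values, cap) {
  stopifnot(cap > 0)
  pmin(pmax(values, 0), cap) / cap
}

#' Construct a signal track
#'
#' A per-base numeric signal over a genome: a named list of per-chromosome
#' numeric vectors or `Rle` objects. Positions outside the stored range (or
#' chromosomes entirely absent from `values` when `strict = FALSE`) return
#' `fill`.
#'
#' @param name channel name.
#' @param values named list of numeric vectors or Rle, one per chromosome.
#' @param fill value for uncovered bases (default 0).
#' @return object of class `signal_track`.
#' @export
signal_track <- function(name, values, fill = 0) {
  stopifnot(is.character(name), length(name) == 1, is.list(values) || methods::is(values, "List"))
  structure(list(name = name, values = values, fill = fill), class = "signal_track")
}

#' Read a signal track from bedGraph or bigWig
#'
#' bedGraph intervals are 0-based half-open on disk; rtracklayer converts them
#' to 1-based closed ranges, and per-base values are materialised as run-length
#' coverage weighted by the score column.
#'
#' @param path file path (`.bedGraph`/`.bg` or `.bw`/`.bigWig`).
#' @param name channel name; defaults to the file base name.
#' @param fill value for uncovered bases.
#' @return a [signal_track()].
#' @export
read_signal_track <- function(path, name = NULL, fill = 0) {
  if (!file.exists(path)) stop("track file not found: ", path)
  if (is.null(name)) name <- sub("\\.[^.]+$", "", basename(path))
  fmt <- if (grepl("\\.(bw|bigwig)$", path, ignore.case = TRUE)) "BigWig" else "bedGraph"
  gr <- rtracklayer::import(path, format = fmt)
  cov <- GenomicRanges::coverage(gr, weight = gr$score)
  signal_track(name, as.list(cov), fill = fill)
}

# per-base values over 1-based closed [start1, end1] with fill outside bounds
track_values <- function(track, chrom, start1, end1) {
  v <- track$values[[chrom]]
  n_out <- end1 - start1 + 1
  if (is.null(v)) return(rep(track$fill, n_out))
  L <- length(v)
  lo <- max(start1, 1); hi <- min(end1, L)
  out <- rep(track$fill, n_out)
  if (lo <= hi) {
    seg <- if (methods::is(v, "Rle")) {
      as.numeric(S4Vectors::window(v, lo, hi))
    } else {
      as.numeric(v[lo:hi])
    }
    out[(lo - start1 + 1):(hi - start1 + 1)] <- seg
  }
  out
}

#' Extract a strand-oriented per-base window around a splice site
#'
#' The genomic window is `[pos - flank, pos + flank)` in 0-based half-open
#' coordinates, where `pos` is the exon boundary. On the minus strand the
#' vector is reversed (and DNA complemented by [dna_window()]) so that index 1
#' is the most 5' position in transcription direction.
#'
#' @param track a [signal_track()].
#' @param chrom chromosome name.
#' @param pos 0-based boundary coordinate of the splice site.
#' @param flank half-window size in bp.
#' @param strand `"+"` or `"-"`.
#' @return numeric vector of length `2 * flank`.
#' @export
track_window <- function(track, chrom, pos, flank, strand = "+") {
  stopifnot(flank > 0, strand %in% c("+", "-"))
  vals <- track_values(track, chrom, pos - flank + 1, pos + flank)
  if (strand == "-") rev(vals) else vals
}

#' Extract a strand-oriented DNA window around a splice site
#'
#' Same geometry as [track_window()]; minus-strand windows are
#' reverse-complemented. Out-of-bounds positions are padded with `N`.
#'
#' @param genome a named `DNAStringSet` (or anything `Biostrings` can subset).
#' @param chrom,pos,flank,strand as in [track_window()].
#' @return character string of length `2 * flank`.
#' @export
dna_window <- function(genome, chrom, pos, flank, strand = "+") {
  stopifnot(flank > 0, strand %in% c("+", "-"))
  if (!(chrom %in% names(genome))) stop("unknown chromosome: ", chrom)
  chr <- genome[[chrom]]
  L <- length(chr)
  s1 <- pos - flank + 1; e1 <- pos + flank
  lo <- max(s1, 1); hi <- min(e1, L)
  seq <- if (lo <= hi) as.character(Biostrings::subseq(chr, lo, hi)) else ""
  pad_l <- strrep("N", max(0, 1 - s1))
  pad_r <- strrep("N", max(0, e1 - L))
  out <- paste0(pad_l, seq, pad_r)
  if (strand == "-") {
    out <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(out)))
  }
  out
}

#' Build the feature matrix for one splice site
#'
#' One-hot DNA (4 channels) plus one clipped/scaled channel per signal track,
#' all oriented 5' to 3' in transcription direction.
#'
#' @param genome named `DNAStringSet`.
#' @param tracks list of [signal_track()] objects.
#' @param chrom,pos,strand site location (0-based boundary coordinate).
#' @param flank half-window in bp (default 100).
#' @param cap cap used by [scale01()] for the signal channels (default 2,
#'   the enrichment cap).
#' @return numeric matrix (2*flank x (4 + n_tracks)) with channel column names.
#' @export
extract_window <- function(genome, tracks, chrom, pos, strand, flank = 100, cap = 2) {
  dna <- one_hot(dna_window(genome, chrom, pos, flank, strand))
  sig <- vapply(tracks, function(tr) {
    scale01(track_window(tr, chrom, pos, flank, strand), cap)
  }, numeric(2 * flank))
  if (length(tracks)) {
    colnames(sig) <- vapply(tracks, `[[`, character(1), "name")
    cbind(dna, sig)
  } else {
    dna
  }
}

#' Reverse the time (position) axis of selected channels
#'
#' @param window feature matrix (positions x channels) with channel column
#'   names.
#' @param channels channel names to reverse; default all non-DNA channels.
#' @return matrix of the same shape.
#' @export
reverse_time <- function(window, channels = setdiff(colnames(window), DNA_CHANNELS)) {
  unknown <- setdiff(channels, colnames(window))
  if (length(unknown)) stop("unknown channels: ", paste(unknown, collapse = ", "))
  ci <- match(channels, colnames(window))
  window[, ci] <- window[rev(seq_len(nrow(window))), ci]
  window
}

#' Reverse the position axis of selected channels across a whole dataset
#'
#' Used by the time-direction reversal test: by default only epigenomic
#' channels are flipped (3' to 5'), leaving the DNA one-hot channels in their
#' native orientation.
#'
#' @param dataset a `splice_dataset`.
#' @param channels channel names to reverse; default all non-DNA channels.
#' @return a `splice_dataset` with reversed windows.
#' @export
reverse_dataset <- function(dataset, channels = setdiff(dataset$channel_names, DNA_CHANNELS)) {
  unknown <- setdiff(channels, dataset$channel_names)
  if (length(unknown)) stop("unknown channels: ", paste(unknown, collapse = ", "))
  ci <- match(channels, dataset$channel_names)
  Tn <- dim(dataset$acceptor)[2]
  for (k in ci) {
    dataset$acceptor[, , k] <- dataset$acceptor[, Tn:1, k]
    dataset$donor[, , k] <- dataset$donor[, Tn:1, k]
  }
  dataset
}

#' Keep a subset of channels in a dataset
#'
#' @param dataset a `splice_dataset`.
#' @param channels channel names to keep; DNA channels are always retained
#'   unless explicitly excluded via `keep_dna = FALSE`.
#' @param keep_dna retain the 4 one-hot DNA channels (default TRUE).
#' @return a `splice_dataset` with the reduced channel registry.
#' @export
subset_channels <- function(dataset, channels, keep_dna = TRUE) {
  keep <- unique(c(if (keep_dna) DNA_CHANNELS, channels))
  unknown <- setdiff(keep, dataset$channel_names)
  if (length(unknown)) stop("unknown channels: ", paste(unknown, collapse = ", "))
  ci <- match(dataset$channel_names[dataset$channel_names %in% keep], dataset$channel_names)
  dataset$acceptor <- dataset$acceptor[, , ci, drop = FALSE]
  dataset$donor <- dataset$donor[, , ci, drop = FALSE]
  dataset$channel_names <- dataset$channel_names[ci]
  dataset
}

#' Build the model dataset: per-event acceptor and donor feature windows
#'
#' For every cassette event, extracts a `2*flank`-position window at the 3'
#' acceptor and at the 5' donor, each with 4 one-hot DNA channels plus one
#' scaled channel per signal track, oriented 5' to 3'. Events on chromosomes
#' absent from the genome are dropped with a message.
#'
#' @param events event table from [cassette_events()] (or the synthetic truth
#'   table): columns `event_id`, `chrom`, `strand`, `acceptor_pos`,
#'   `donor_pos`.
#' @param genome named `DNAStringSet`.
#' @param tracks list of [signal_track()] objects (possibly empty for a
#'   DNA-only dataset).
#' @param flank half-window in bp per splice site (default 100, i.e. 200
#'   positions per site and a 400 bp total span per event).
#' @param labels optional named 0/1 vector (names = event ids): 1 = included.
#' @param cap signal scaling cap (default 2).
#' @return object of class `splice_dataset`: arrays `acceptor` and `donor`
#'   (events x positions x channels), `labels`, `event_id`, `channel_names`,
#'   `flank`.
#' @export
build_dataset <- function(events, genome, tracks = list(), flank = 100,
                          labels = NULL, cap = 2) {
  stopifnot(flank > 0)
  keep <- events$chrom %in% names(genome)
  if (any(!keep)) {
    message("dropping ", sum(!keep), " event(s) on contigs missing from the genome")
    events <- events[keep, , drop = FALSE]
  }
  n <- nrow(events)
  if (n == 0) stop("no events left to featurise")
  track_names <- unname(vapply(tracks, `[[`, character(1), "name"))
  channel_names <- c(DNA_CHANNELS, track_names)
  Tn <- 2 * flank
  C <- length(channel_names)
  acc <- array(0, c(n, Tn, C))
  don <- array(0, c(n, Tn, C))
  for (i in seq_len(n)) {
    acc[i, , ] <- extract_window(genome, tracks, events$chrom[i],
                                 events$acceptor_pos[i], events$strand[i], flank, cap)
    don[i, , ] <- extract_window(genome, tracks, events$chrom[i],
                                 events$donor_pos[i], events$strand[i], flank, cap)
  }
  lab <- if (is.null(labels)) rep(NA_integer_, n) else as.integer(labels[events$event_id])
  structure(list(acceptor = acc, donor = don, labels = lab,
                 event_id = events$event_id, channel_names = channel_names,
                 flank = flank),
            class = "splice_dataset")
}

#' @export
print.splice_dataset <- function(x, ...) {
  cat(sprintf("splice_dataset: %d events, %d positions/site (flank %d), %d channels\n",
              length(x$event_id), dim(x$acceptor)[2], x$flank,
              length(x$channel_names)))
  cat("channels:", paste(x$channel_names, collapse = ", "), "\n")
  if (!all(is.na(x$labels))) {
    cat(sprintf("labels: %d included / %d skipped\n",
                sum(x$labels == 1, na.rm = TRUE), sum(x$labels == 0, na.rm = TRUE)))
  }
  invisible(x)
}
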