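#' Parse exon annotation from a GENCODE-style GTF
#'
#' Reads `exon` features, keeps protein-coding genes (when annotated via a
#' `gene_type` attribute), rejects records without a usable strand, and
#' removes exons of genes annotated on both chromosome X and chromosome Y
#' (pseudoautosomal-style ambiguous duplicates). GTF coordinates are 1-based
#' inclusive; the returned `GRanges` keeps that convention, while downstream
#' event tables carry 0-based half-open boundary coordinates.
#'
#' @param gtf_file path to a GTF file.
#' @param protein_coding_only keep only genes with
#'   `gene_type == "protein_coding"` when the attribute is present.
#' @param drop_xy_ambiguous drop genes annotated on both chrX and chrY.
#' @return `GRanges` of exons with metadata columns `gene_id`,
#'   `transcript_id`, `exon_id`, `exon_rank` (ordinal position within the
#'   transcript in transcription direction).
#' @export
parse_annotation <- function(gtf_file, protein_coding_only = TRUE,
                             drop_xy_ambiguous = TRUE) {
  if (!file.exists(gtf_file)) stop("GTF file not found: ", gtf_file)
  gr <- rtracklayer::import(gtf_file, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0) stop("no exon features in ", gtf_file)
  if (is.null(gr$gene_id) || is.null(gr$transcript_id)) {
    stop("GTF exon records must carry gene_id and transcript_id attributes")
  }
  bad_strand <- as.character(GenomicRanges::strand(gr)) == "*"
  if (any(bad_strand)) {
    warning("rejecting ", sum(bad_strand), " exon record(s) with unknown strand")
    gr <- gr[!bad_strand]
  }
  if (protein_coding_only && !is.null(gr$gene_type)) {
    gr <- gr[gr$gene_type == "protein_coding"]
  }
  if (drop_xy_ambiguous) {
    chrom <- as.character(GenomicRanges::seqnames(gr))
    on_x <- unique(gr$gene_id[chrom %in% c("chrX", "X")])
    on_y <- unique(gr$gene_id[chrom %in% c("chrY", "Y")])
    ambiguous <- intersect(on_x, on_y)
    if (length(ambiguous)) gr <- gr[!(gr$gene_id %in% ambiguous)]
  }
  if (is.null(gr$exon_id)) {
    gr$exon_id <- sprintf("%s:%d-%d:%s", as.character(GenomicRanges::seqnames(gr)),
                          GenomicRanges::start(gr), GenomicRanges::end(gr),
                          as.character(GenomicRanges::strand(gr)))
  }
  # rank within each transcript in transcription direction
  if (!is.null(gr$exon_number)) {
    gr$exon_rank <- as.integer(as.character(gr$exon_number))
  } else {
    ord <- order(gr$transcript_id, GenomicRanges::start(gr))
    gr <- gr[ord]
    rk <- stats::ave(GenomicRanges::start(gr), gr$transcript_id,
                     FUN = function(x) seq_along(x))
    neg <- as.character(GenomicRanges::strand(gr)) == "-"
    n_per <- stats::ave(GenomicRanges::start(gr), gr$transcript_id,
                        FUN = function(x) rep(length(x), length(x)))
    gr$exon_rank <- as.integer(ifelse(neg, n_per - rk + 1, rk))
  }
  gr
}

#' Collapse exons to unique genomic intervals
#'
#' Duplicate exons shared by multiple transcript isoforms (same chromosome,
#' start, end and strand) are collapsed to one record.
#'
#' @param exons `GRanges` from [parse_annotation()].
#' @return de-duplicated `GRanges`.
#' @export
unique_exons <- function(exons) {
  key <- paste(as.character(GenomicRanges::seqnames(exons)),
               GenomicRanges::start(exons), GenomicRanges::end(exons),
               as.character(GenomicRanges::strand(exons)))
  exons[!duplicated(key)]
}

#' Enumerate cassette-candidate events (internal exons)
#'
#' Transcripts with fewer than three exons yield no events; the first and
#' last exon of every transcript are excluded, and every remaining internal
#' exon becomes one candidate event with strand-aware acceptor (3', intron to
#' exon) and donor (5', exon to intron) splice-site coordinates. Transcripts
#' whose exons disagree on strand are rejected with a diagnostic.
#'
#' @param exons `GRanges` from [parse_annotation()].
#' @param unique_events collapse events duplicated across isoforms (same
#'   chromosome/start/end/strand); default TRUE.
#' @return data frame with one row per event: `event_id`, `exon_id`,
#'   `gene_id`, `chrom`, `start`, `end` (0-based half-open exon interval),
#'   `strand`, `exon_length`, `acceptor_pos`, `donor_pos` (0-based boundary
#'   coordinates).
#' @export
cassette_events <- function(exons, unique_events = TRUE) {
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(exons)),
    start1 = GenomicRanges::start(exons),
    end1 = GenomicRanges::end(exons),
    strand = as.character(GenomicRanges::strand(exons)),
    gene_id = exons$gene_id, transcript_id = exons$transcript_id,
    exon_id = exons$exon_id, exon_rank = exons$exon_rank,
    stringsAsFactors = FALSE)
  pieces <- split(df, df$transcript_id)
  rows <- lapply(pieces, function(tx) {
    if (length(unique(tx$strand)) != 1) {
      warning("transcript ", tx$transcript_id[1],
              " has inconsistent strand across exons; skipped")
      return(NULL)
    }
    if (nrow(tx) < 3) return(NULL)
    tx <- tx[order(tx$exon_rank), , drop = FALSE]
    internal <- tx[-c(1, nrow(tx)), , drop = FALSE]
    s0 <- internal$start1 - 1L   # 0-based half-open
    e0 <- internal$end1
    plus <- internal$strand == "+"
    data.frame(
      event_id = internal$exon_id, exon_id = internal$exon_id,
      gene_id = internal$gene_id, chrom = internal$chrom,
      start = s0, end = e0, strand = internal$strand,
      exon_length = e0 - s0,
      acceptor_pos = ifelse(plus, s0, e0),
      donor_pos = ifelse(plus, e0, s0),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    stop("no internal exons found; are all transcripts shorter than 3 exons?")
  }
  rownames(out) <- NULL
  if (unique_events) {
    key <- paste(out$chrom, out$start, out$end, out$strand)
    out <- out[!duplicated(key), , drop = FALSE]
  }
  out
}

#' Write cassette events as BED6
#'
#' BED is 0-based half-open; name = event id, score = 0.
#'
#' @param events event table from [cassette_events()].
#' @param path output file.
#' @return invisibly, the path.
#' @export
write_events_bed <- function(events, path) {
  gr <- GenomicRanges::GRanges(
    seqnames = events$chrom,
    ranges = IRanges::IRanges(start = events$start + 1L, end = events$end),
    strand = events$strand)
  gr$name <- events$event_id
  gr$score <- 0L
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read cassette events back from BED6
#'
#' Reconstructs the strand-aware acceptor/donor boundary coordinates from the
#' exon interval.
#'
#' @param path BED file written by [write_events_bed()].
#' @return event table in the same layout as [cassette_events()] (without
#'   `gene_id`).
#' @export
read_events_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  s0 <- GenomicRanges::start(gr) - 1L
  e0 <- GenomicRanges::end(gr)
  strand <- as.character(GenomicRanges::strand(gr))
  plus <- strand == "+"
  data.frame(
    event_id = gr$name, exon_id = gr$name,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = s0, end = e0, strand = strand,
    exon_length = e0 - s0,
    acceptor_pos = ifelse(plus, s0, e0),
    donor_pos = ifelse(plus, e0, s0),
    stringsAsFactors = FALSE)
}
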