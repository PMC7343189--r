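#' Metagene enrichment profile around splice sites, stratified by PSI band
#'
#' For each PSI band (`high` >= 80%, inclusion; `mid` 40-60%; `low` <= 20%,
#' skipping) and each splice site (3' acceptor, 5' donor), computes the
#' per-position arithmetic mean of the strand-oriented signal across events.
#' Position 0 is the first base after the boundary in transcription
#' direction (exonic for the acceptor, intronic for the donor); negative
#' positions are upstream of the boundary. Empty bands are omitted with a
#' warning.
#'
#' @param events event table ([cassette_events()] layout).
#' @param track a [signal_track()].
#' @param psi named numeric vector of PSI percentages (names = event ids), or
#'   a data frame with columns `event_id`, `psi`.
#' @param flank half-window in bp (default 500).
#' @return data frame: `site` (acceptor/donor), `position`
#'   (-flank .. flank-1), `boundary` (e.g. `acceptor_intron` for the intronic
#'   side of the 3' splice site), `psi_class`, `mean_signal`, `n_events`.
#' @export
aggregate_profile <- function(events, track, psi, flank = 500) {
  if (is.data.frame(psi)) psi <- stats::setNames(psi$psi, psi$event_id)
  cls <- psi_band(psi[events$event_id])
  positions <- seq(-flank, flank - 1)
  out <- list()
  for (band in c("low", "mid", "high")) {
    sel <- which(!is.na(cls) & cls == band)
    if (length(sel) == 0) {
      warning("no events in PSI band '", band, "'; omitted")
      next
    }
    for (site in c("acceptor", "donor")) {
      pos_col <- paste0(site, "_pos")
      mat <- vapply(sel, function(i) {
        track_window(track, events$chrom[i], events[[pos_col]][i], flank,
                     events$strand[i])
      }, numeric(2 * flank))
      boundary <- paste0(site, "_", switch(site,
        acceptor = ifelse(positions < 0, "intron", "exon"),
        donor = ifelse(positions < 0, "exon", "intron")))
      out[[length(out) + 1]] <- data.frame(
        site = site, position = positions, boundary = boundary,
        psi_class = band, mean_signal = rowMeans(mat),
        n_events = length(sel), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0) stop("no events fall in any PSI band")
  do.call(rbind, out)
}

#' Star annotation bins for p-values
#'
#' `ns`: 0.05 < p <= 1; `*`: 0.01 < p <= 0.05; `**`: 0.001 < p <= 0.01;
#' `***`: 0.0001 < p <= 0.001; `****`: p <= 0.0001.
#'
#' @param p numeric p-values.
#' @return character vector of star annotations.
#' @export
stars_from_p <- function(p) {
  ifelse(p <= 1e-4, "****",
         ifelse(p <= 1e-3, "***",
                ifelse(p <= 0.01, "**",
                       ifelse(p <= 0.05, "*", "ns"))))
}

#' Rank-sum comparison of segment-level signal between PSI bands
#'
#' Each event is reduced to its mean signal within each segment (intervals in
#' bp relative to the 3' acceptor site, transcription direction, half-open).
#' For every segment and pair of PSI bands a two-sided Mann-Whitney-Wilcoxon
#' test is run: exact when the combined sample size is at most 20 and the
#' data are tie-free, normal approximation with continuity correction
#' otherwise. Pairs with fewer than two events in a group are skipped.
#'
#' The default scheme tiles [-100, 100): `A` = [-100,-50) distal intronic,
#' `C` = [-50,0) proximal intronic (the branch-point region), `B` = [0,50)
#' proximal exonic, `D` = [50,100) distal exonic.
#'
#' @param events event table.
#' @param track a [signal_track()].
#' @param psi named PSI vector or data frame (`event_id`, `psi`).
#' @param segments named list of `c(start, end)` intervals relative to the
#'   acceptor boundary.
#' @param site `"acceptor"` (default) or `"donor"`.
#' @return data frame: `segment`, `group1`, `group2`, `statistic` (rank-sum
#'   U), `p_value`, `stars`.
#' @export
compare_segments <- function(events, track, psi,
                             segments = list(A = c(-100, -50), C = c(-50, 0),
                                             B = c(0, 50), D = c(50, 100)),
                             site = c("acceptor", "donor")) {
  site <- match.arg(site)
  if (is.data.frame(psi)) psi <- stats::setNames(psi$psi, psi$event_id)
  cls <- psi_band(psi[events$event_id])
  span <- max(abs(unlist(segments)))
  pos_col <- paste0(site, "_pos")
  seg_means <- lapply(names(segments), function(sg) {
    a <- segments[[sg]][1]; b <- segments[[sg]][2]
    vapply(seq_len(nrow(events)), function(i) {
      w <- track_window(track, events$chrom[i], events[[pos_col]][i], span,
                        events$strand[i])
      # window index 1 corresponds to position -span
      mean(w[(a + span + 1):(b + span)])
    }, numeric(1))
  })
  names(seg_means) <- names(segments)
  bands <- c("low", "mid", "high")
  pairs <- utils::combn(bands, 2, simplify = FALSE)
  rows <- list()
  for (sg in names(segments)) {
    for (pr in pairs) {
      x <- seg_means[[sg]][!is.na(cls) & cls == pr[1]]
      y <- seg_means[[sg]][!is.na(cls) & cls == pr[2]]
      if (length(x) < 2 || length(y) < 2) next
      exact <- (length(x) + length(y) <= 20) && !anyDuplicated(c(x, y))
      wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                                correct = TRUE))
      rows[[length(rows) + 1]] <- data.frame(
        segment = sg, group1 = pr[1], group2 = pr[2],
        statistic = unname(wt$statistic), p_value = wt$p.value,
        stars = stars_from_p(wt$p.value), stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) stop("no PSI band pair had at least two events per group")
  do.call(rbind, rows)
}

#' Correlation of exon expression with splice-site enrichment
#'
#' Pearson correlation between per-exon FPKM and mean signal near the splice
#' site, plus rank-sum comparisons of signal between expression groups
#' (FPKM tertiles by default).
#'
#' @param fpkm numeric vector of exon FPKM values.
#' @param signal numeric vector of per-event mean signal (same order).
#' @param n_groups number of expression groups (default 3, tertiles).
#' @return list: `pcc` (Pearson correlation, `NA` with `reason` when an input
#'   has zero variance), `n`, `groups` (per-group mean signal) and
#'   `comparisons` (pairwise rank-sum tests with stars).
#' @export
correlate_expression_enrichment <- function(fpkm, signal, n_groups = 3) {
  stopifnot(length(fpkm) == length(signal))
  ok <- is.finite(fpkm) & is.finite(signal)
  fpkm <- fpkm[ok]; signal <- signal[ok]
  if (length(fpkm) < 3) stop("need at least 3 paired finite observations")
  if (stats::sd(fpkm) == 0 || stats::sd(signal) == 0) {
    return(list(pcc = NA_real_, n = length(fpkm),
                reason = "zero variance in fpkm or signal",
                groups = NULL, comparisons = NULL))
  }
  pcc <- stats::cor(fpkm, signal, method = "pearson")
  qs <- stats::quantile(fpkm, probs = seq(0, 1, length.out = n_groups + 1))
  grp <- cut(fpkm, breaks = unique(qs), include.lowest = TRUE,
             labels = FALSE)
  groups <- data.frame(group = sort(unique(grp)),
                       n = as.vector(table(grp)),
                       mean_signal = tapply(signal, grp, mean))
  pairs <- utils::combn(sort(unique(grp)), 2, simplify = FALSE)
  comparisons <- do.call(rbind, lapply(pairs, function(pr) {
    wt <- suppressWarnings(stats::wilcox.test(signal[grp == pr[1]],
                                              signal[grp == pr[2]]))
    data.frame(group1 = pr[1], group2 = pr[2], p_value = wt$p.value,
               stars = stars_from_p(wt$p.value))
  }))
  list(pcc = pcc, n = length(fpkm), groups = groups, comparisons = comparisons)
}

#' Bin RNA-binding-protein peaks around splice sites
#'
#' Peaks below the score filter are removed and the remaining peaks reduced
#' to their midpoints. For every event splice site, midpoints within `span`
#' bp are assigned to `bin_width` bp bins by their transcription-direction
#' offset from the boundary, separately for the 3' acceptor and the 5' donor.
#' Frequency is the peak count divided by the bin width; a per-site
#' normalised frequency divides additionally by the number of splice sites.
#'
#' @param peaks data frame with columns `chrom`, `start` (0-based), `end`,
#'   `name` (factor), `score`, or a `GRanges` with `name`/`score` metadata.
#' @param events event table.
#' @param bin_width bin size in bp (default 100).
#' @param span half-extent around each site in bp (default 1000).
#' @param score_min minimum peak score kept (default 1000).
#' @param factors optional factor-name subset (e.g. hnRNP/SR-family splicing
#'   factors).
#' @return data frame: `site`, `bin_start` (relative bp, -span .. span -
#'   bin_width), `count`, `frequency` (per bp), `frequency_per_site`.
#' @export
bin_rbp_peaks <- function(peaks, events, bin_width = 100, span = 1000,
                          score_min = 1000, factors = NULL) {
  if (methods::is(peaks, "GRanges")) {
    peaks <- data.frame(chrom = as.character(GenomicRanges::seqnames(peaks)),
                        start = GenomicRanges::start(peaks) - 1L,
                        end = GenomicRanges::end(peaks),
                        name = peaks$name, score = peaks$score,
                        stringsAsFactors = FALSE)
  }
  bins <- seq(-span, span - bin_width, by = bin_width)
  empty <- function() data.frame(site = rep(c("acceptor", "donor"), each = length(bins)),
                                 bin_start = rep(bins, 2), count = 0,
                                 frequency = 0, frequency_per_site = 0)
  n_sites <- nrow(events)
  if (is.null(peaks) || nrow(peaks) == 0) return(empty())
  peaks <- peaks[peaks$score >= score_min, , drop = FALSE]
  if (!is.null(factors)) peaks <- peaks[peaks$name %in% factors, , drop = FALSE]
  if (nrow(peaks) == 0) return(empty())
  mid <- floor((peaks$start + peaks$end) / 2)
  out <- list()
  for (site in c("acceptor", "donor")) {
    pos <- events[[paste0(site, "_pos")]]
    counts <- stats::setNames(rep(0, length(bins)), bins)
    for (i in seq_len(n_sites)) {
      same <- peaks$chrom == events$chrom[i]
      if (!any(same)) next
      d <- if (events$strand[i] == "+") mid[same] - pos[i] else pos[i] - 1 - mid[same]
      d <- d[d >= -span & d < span]
      if (length(d)) {
        b <- table(factor(floor(d / bin_width) * bin_width, levels = bins))
        counts <- counts + as.vector(b)
      }
    }
    out[[site]] <- data.frame(site = site, bin_start = bins,
                              count = as.vector(counts),
                              frequency = as.vector(counts) / bin_width,
                              frequency_per_site = as.vector(counts) / (bin_width * n_sites),
                              stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Default splicing-factor name set (hnRNP and SR families)
#'
#' A convenience set of factor names commonly used to restrict RBP profiles
#' to splicing-related factors.
#'
#' @return character vector of factor names.
#' @export
splicing_factor_names <- function() {
  c("HNRNPA1", "HNRNPA2B1", "HNRNPC", "HNRNPK", "HNRNPL", "HNRNPM",
    "HNRNPU", "SRSF1", "SRSF2", "SRSF5", "SRSF7", "SRSF9", "U2AF1", "U2AF2",
    "SF3B4", "TRA2A", "TRA2B")
}
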