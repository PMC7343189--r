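#' Exon-level FPKM
#'
#' `count / ((exon_length_bp / 1000) * (total_mapped_reads / 1e6))` --
#' fragments per kilobase of exon per million mapped reads, computed per exon
#' so the measure is agnostic to overall transcript structure.
#'
#' @param count non-negative read count(s) on the exon.
#' @param exon_length_bp exon length(s) in bp (> 0).
#' @param total_mapped_reads library size (> 0).
#' @return numeric FPKM.
#' @export
compute_fpkm <- function(count, exon_length_bp, total_mapped_reads) {
  if (any(exon_length_bp <= 0)) stop("exon_length_bp must be positive")
  if (any(total_mapped_reads <= 0)) stop("total_mapped_reads must be positive")
  count / ((exon_length_bp / 1000) * (total_mapped_reads / 1e6))
}

#' Binarise exon expression
#'
#' An exon counts as expressed (included) when its FPKM is greater than or
#' equal to the threshold (default 1).
#'
#' @param fpkm numeric FPKM values.
#' @param threshold inclusion threshold (default 1).
#' @return logical vector.
#' @export
binarize_expression <- function(fpkm, threshold = 1) {
  stopifnot(all(fpkm >= 0))
  fpkm >= threshold
}

#' Junction-normalised percent spliced in (PSI)
#'
#' Inclusion-supporting reads are normalised by the number of distinct
#' positions that can produce them (`exon_length + fragment_length`),
#' exclusion-supporting reads by `fragment_length`:
#' `psi = 100 * (F_incl / (L_i + L_f)) / (F_incl / (L_i + L_f) + F_excl / L_f)`.
#' Events with no junction evidence at all return `NA` (class "undefined").
#'
#' @param f_incl reads supporting inclusion.
#' @param f_excl reads supporting exclusion.
#' @param exon_length exon size(s) `L_i` in bp (> 0).
#' @param fragment_length fragment length `L_f` in bp (> 0, default 100).
#' @return PSI in percent (0-100), `NA` where `f_incl + f_excl == 0`.
#' @export
compute_psi <- function(f_incl, f_excl, exon_length, fragment_length = 100) {
  if (any(fragment_length <= 0)) stop("fragment_length must be positive")
  if (any(exon_length <= 0)) stop("exon_length must be positive")
  if (any(f_incl < 0) || any(f_excl < 0)) stop("junction counts must be non-negative")
  fi <- f_incl / (exon_length + fragment_length)
  fe <- f_excl / fragment_length
  psi <- 100 * fi / (fi + fe)
  psi[f_incl + f_excl == 0] <- NA_real_
  psi
}

#' Classify PSI into skipped / mid / included
#'
#' Cutoff scheme: `psi <= low` is skipped, `psi >= high` is included,
#' in between is mid; `NA` PSI maps to "undefined".
#'
#' @param psi PSI in percent.
#' @param low skipping cutoff (default 20).
#' @param high inclusion cutoff (default 80).
#' @return character vector in `{skipped, mid, included, undefined}`.
#' @export
classify_psi <- function(psi, low = 20, high = 80) {
  out <- ifelse(is.na(psi), "undefined",
                ifelse(psi <= low, "skipped",
                       ifelse(psi >= high, "included", "mid")))
  as.character(out)
}

#' Band classification used by enrichment profiling
#'
#' `low` (<= 20% PSI, skipping), `mid` (40-60%), `high` (>= 80%, inclusion);
#' PSI values outside all three bands return `NA`.
#'
#' @param psi PSI in percent.
#' @return character vector in `{low, mid, high}` or `NA`.
#' @export
psi_band <- function(psi) {
  out <- rep(NA_character_, length(psi))
  out[!is.na(psi) & psi <= 20] <- "low"
  out[!is.na(psi) & psi >= 40 & psi <= 60] <- "mid"
  out[!is.na(psi) & psi >= 80] <- "high"
  out
}

#' Quantify exon expression and splicing from count tables
#'
#' Joins per-exon read counts with per-event junction counts, computes FPKM,
#' the binary expression label, PSI and its class.
#'
#' @param counts data frame with columns `exon_id`, `count`.
#' @param junctions data frame with columns `exon_id`, `f_incl`, `f_excl`.
#' @param exon_lengths named vector of exon lengths in bp (names = exon ids).
#' @param total_mapped_reads library size; default `sum(counts$count)`.
#' @param fragment_length fragment length in bp (default 100).
#' @param fpkm_threshold expression threshold (default 1).
#' @return data frame with columns `exon_id`, `count`, `fpkm`, `expressed`,
#'   `f_incl`, `f_excl`, `psi`, `psi_class`.
#' @export
quantify_exons <- function(counts, junctions, exon_lengths,
                           total_mapped_reads = NULL, fragment_length = 100,
                           fpkm_threshold = 1) {
  stopifnot(all(c("exon_id", "count") %in% names(counts)),
            all(c("exon_id", "f_incl", "f_excl") %in% names(junctions)))
  if (is.null(total_mapped_reads)) total_mapped_reads <- sum(counts$count)
  df <- merge(counts, junctions, by = "exon_id", all = TRUE)
  df$count[is.na(df$count)] <- 0
  len <- exon_lengths[df$exon_id]
  if (any(is.na(len))) stop("missing exon lengths for: ",
                            paste(utils::head(df$exon_id[is.na(len)]), collapse = ", "))
  df$fpkm <- compute_fpkm(df$count, len, total_mapped_reads)
  df$expressed <- binarize_expression(df$fpkm, fpkm_threshold)
  df$psi <- compute_psi(df$f_incl, df$f_excl, len, fragment_length)
  df$psi_class <- classify_psi(df$psi)
  df
}

#' Read a tab-separated count table
#'
#' @param path TSV with a header line.
#' @return data frame.
#' @export
read_counts_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a table as TSV
#'
#' @param df data frame.
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
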