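# Echo analysis: superimpose the smoothed SNV profile in fixed flanks around
# qualifying SV peaks and quantify the central SNV elevation relative to the
# genomic average.

#' Superimposed SNV profile around SV peaks
#'
#' For every peak, extracts the smoothed SNV values at bin offsets
#' `-flank .. +flank` around the peak bin and averages them across peaks per
#' offset. Offsets falling off a chromosome contribute nothing: each offset's
#' mean divides by the number of in-bounds contributions (no zero padding,
#' which would fabricate depletion at chromosome edges). Peaks are aligned at
#' bin centers; resolution is bounded by `bin_size`.
#'
#' @param sv_peaks Data frame from [find_peaks()], already filtered at the
#'   desired fold threshold (2 or 5 in these analyses).
#' @param snv_smoothed Smoothed SNV `binned_track` sharing the grid of the
#'   track the peaks were called on.
#' @param flank_bp Flank half-width in base pairs; must be a multiple of the
#'   bin size. Default 15 Mb.
#' @return Object of class `echo_profile`: list with offsets_bp,
#'   mean_snv_by_offset, n_contributing (per offset), n_peaks,
#'   snv_genomic_average, flank_bp, bin_size. With zero qualifying peaks an
#'   empty profile (n_peaks = 0, all-NA means) is returned.
#' @export
echo_profile <- function(sv_peaks, snv_smoothed, flank_bp = 15e6) {
  stopifnot(inherits(snv_smoothed, "binned_track"))
  bin_size <- snv_smoothed$bin_size
  if (flank_bp %% bin_size != 0)
    stop("flank_bp must be a multiple of the bin size")
  h <- as.integer(flank_bp / bin_size)
  offsets <- (-h):h
  n_off <- length(offsets)
  sums <- numeric(n_off)
  counts <- integer(n_off)
  for (i in seq_len(nrow(sv_peaks))) {
    ch <- sv_peaks$chrom[i]
    v <- snv_smoothed$values[[ch]]
    if (is.null(v)) stop("peak chromosome absent from SNV track: ", ch)
    centre <- sv_peaks$bin_index[i] + 1L  # 1-based
    idx <- centre + offsets
    ok <- idx >= 1L & idx <= length(v)
    sums[ok] <- sums[ok] + v[idx[ok]]
    counts[ok] <- counts[ok] + 1L
  }
  means <- ifelse(counts > 0L, sums / pmax(counts, 1L), NA_real_)
  structure(list(
    offsets_bp = offsets * bin_size,
    mean_snv_by_offset = means,
    n_contributing = counts,
    n_peaks = nrow(sv_peaks),
    snv_genomic_average = genomic_average(snv_smoothed),
    flank_bp = flank_bp, bin_size = bin_size),
    class = "echo_profile")
}

#' @export
print.echo_profile <- function(x, ...) {
  cat(sprintf("<echo_profile> %d peak(s), flank %.0f bp, bin %.0f bp, baseline %.4g\n",
              x$n_peaks, x$flank_bp, x$bin_size, x$snv_genomic_average))
  invisible(x)
}

#' Central elevation of an echo profile
#'
#' Mean of the profile over offsets within `center_halfwidth_bp` of the peak,
#' divided by the SNV genomic average. Values above 1 indicate SNV elevation
#' centered on SV peaks; the score is invariant under uniform scaling of the
#' SNV track. The default half-width of 1 Mb (one bin at the default grid)
#' matches the scale at which SV-proximal enrichment is quantified.
#'
#' @param profile An [echo_profile()].
#' @param center_halfwidth_bp Central window half-width; must be smaller than
#'   the profile's flank.
#' @return A single ratio.
#' @export
echo_enrichment_score <- function(profile, center_halfwidth_bp = 1e6) {
  stopifnot(inherits(profile, "echo_profile"))
  if (profile$n_peaks == 0L) stop("empty profile: no qualifying peaks")
  if (center_halfwidth_bp >= profile$flank_bp)
    stop("center_halfwidth_bp must be < flank_bp")
  if (profile$snv_genomic_average <= 0) stop("zero genomic average")
  sel <- abs(profile$offsets_bp) <= center_halfwidth_bp &
    profile$n_contributing > 0L
  if (!any(sel)) stop("no in-bounds central offsets")
  mean(profile$mean_snv_by_offset[sel]) / profile$snv_genomic_average
}

#' Export an echo profile as TSV
#'
#' Columns: offset_bp, mean_snv, n_contributing.
#'
#' @param profile An [echo_profile()].
#' @param path Output path.
#' @export
write_echo_profile <- function(profile, path) {
  df <- data.frame(offset_bp = profile$offsets_bp,
                   mean_snv = profile$mean_snv_by_offset,
                   n_contributing = profile$n_contributing)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
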