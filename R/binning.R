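# Fixed-width per-chromosome tracks: the substrate for genomic averages,
# moving-average smoothing, peak calling and the echo analysis.

#' Construct a binned track
#'
#' @param assembly A [genome_assembly()].
#' @param bin_size Bin width in base pairs (>= 1).
#' @param values Named list (one numeric vector per chromosome, assembly
#'   order) with `ceiling(length / bin_size)` entries each. If NULL, all-zero.
#' @return Object of class `binned_track`.
#' @export
binned_track <- function(assembly, bin_size, values = NULL) {
  stopifnot(inherits(assembly, "genome_assembly"))
  if (!is.numeric(bin_size) || length(bin_size) != 1L || bin_size < 1)
    stop("bin_size must be a single number >= 1")
  n_bins <- ceiling(assembly$length / bin_size)
  if (is.null(values)) {
    values <- lapply(n_bins, function(n) numeric(n))
    names(values) <- assembly$chrom
  } else {
    if (!identical(sort(names(values)), sort(assembly$chrom)))
      stop("values must be named by assembly chromosomes")
    values <- values[assembly$chrom]
    ok <- vapply(assembly$chrom,
                 function(ch) length(values[[ch]]) == n_bins[[ch]], logical(1))
    if (!all(ok)) stop("per-chromosome value lengths must equal ceiling(length/bin_size)")
  }
  structure(list(assembly = assembly, bin_size = bin_size, values = values),
            class = "binned_track")
}

#' @export
print.binned_track <- function(x, ...) {
  cat(sprintf("<binned_track> bin_size=%.0f, %d chromosome(s), %d bins, mean %.4g\n",
              x$bin_size, length(x$values), sum(lengths(x$values)),
              mean(unlist(x$values, use.names = FALSE))))
  invisible(x)
}

track_values <- function(track) unlist(track$values, use.names = FALSE)

same_grid <- function(a, b) {
  identical(a$assembly$chrom, b$assembly$chrom) &&
    identical(unname(a$assembly$length), unname(b$assembly$length)) &&
    a$bin_size == b$bin_size
}

#' Count positions into fixed-width bins
#'
#' Bin `i` (0-based) of a chromosome holds positions `p` with
#' `floor(p / bin_size) == i`; the total over all bins always equals the
#' number of input positions.
#'
#' @param positions Named list of numeric 0-based position vectors (names are
#'   chromosomes), or an [snv_set()] (its positions are used), or the data
#'   frame returned by [breakpoints()].
#' @param assembly A [genome_assembly()]; ignored when `positions` carries one.
#' @param bin_size Bin width in base pairs.
#' @return A `binned_track` of raw counts.
#' @export
bin_counts <- function(positions, assembly = NULL, bin_size = 1e6) {
  if (inherits(positions, "snv_set")) {
    assembly <- assembly_of(positions)
    positions <- positions_by_chrom(positions$chrom, positions$pos, assembly)
  } else if (is.data.frame(positions) &&
             all(c("chrom", "pos") %in% names(positions))) {
    if (is.null(assembly)) assembly <- assembly_of(positions)
    positions <- positions_by_chrom(positions$chrom, positions$pos, assembly)
  }
  stopifnot(inherits(assembly, "genome_assembly"))
  if (bin_size < 1) stop("bin_size must be >= 1")
  unknown <- setdiff(names(positions), assembly$chrom)
  if (length(unknown)) stop("positions on unknown chromosome(s): ",
                            paste(unknown, collapse = ", "))
  track <- binned_track(assembly, bin_size)
  for (ch in names(positions)) {
    p <- positions[[ch]]
    if (length(p) == 0L) next
    if (any(p < 0 | p >= assembly$length[[ch]]))
      stop("position outside chromosome ", ch)
    idx <- floor(p / bin_size) + 1
    track$values[[ch]] <- as.numeric(
      tabulate(idx, nbins = length(track$values[[ch]])))
  }
  track
}

#' Centered moving average of a track
#'
#' Smooths each chromosome independently with a centered window of
#' `span_bins` bins. At chromosome edges the window is truncated to in-bounds
#' bins and the mean divides by the truncated window size (no zero padding).
#'
#' @param track A `binned_track`.
#' @param span_bins Odd positive window width in bins. The default 11 realizes
#'   a 10 Mb smoothing span over 1 Mb bins (bin of interest +/- 5 Mb).
#' @return A smoothed `binned_track`.
#' @export
moving_average <- function(track, span_bins = 11L) {
  stopifnot(inherits(track, "binned_track"))
  if (span_bins < 1 || span_bins %% 2 == 0)
    stop("span_bins must be an odd positive integer")
  h <- (span_bins - 1) / 2
  track$values <- lapply(track$values, function(v) {
    n <- length(v)
    if (n == 0L) return(v)
    cs <- c(0, cumsum(v))
    i <- seq_len(n)
    lo <- pmax(i - h, 1); hi <- pmin(i + h, n)
    (cs[hi + 1] - cs[lo]) / (hi - lo + 1)
  })
  track
}

#' Genome-wide mean bin value
#'
#' The baseline for every fold-enrichment threshold. Zero-count bins (e.g.
#' centromeres) are included unless excluded via `mask`: bins whose midpoint
#' falls in a masked interval are dropped from the mean.
#'
#' @param track A `binned_track`.
#' @param mask Optional data frame of 0-based half-open intervals
#'   (chrom, start, end), e.g. from [read_bed()].
#' @return A single number.
#' @export
genomic_average <- function(track, mask = NULL) {
  stopifnot(inherits(track, "binned_track"))
  v <- track_values(track)
  if (length(v) == 0L) stop("empty track")
  if (is.null(mask)) return(mean(v))
  keep <- !track_values(mask_bins(track, mask))
  if (!any(keep)) stop("all bins masked")
  mean(v[keep])
}

# logical track: TRUE where the bin midpoint lies in a masked interval
mask_bins <- function(track, mask) {
  out <- track
  out$values <- lapply(names(track$values), function(ch) {
    n <- length(track$values[[ch]])
    mid <- (seq_len(n) - 1) * track$bin_size + track$bin_size / 2
    m <- mask[mask$chrom == ch, , drop = FALSE]
    flag <- rep(FALSE, n)
    for (k in seq_len(nrow(m)))
      flag <- flag | (mid >= m$start[k] & mid < m$end[k])
    flag
  })
  names(out$values) <- names(track$values)
  out
}

#' Call peaks on a smoothed track
#'
#' A peak is a strict local maximum of the smoothed values whose height is at
#' least `fold_threshold` times the genomic average. Plateaus (runs of equal
#' values strictly above both flanking values) yield one peak at the run's
#' midpoint bin, ties broken leftward; chromosome-terminal bins qualify when
#' strictly greater than their single neighbor.
#'
#' @param smoothed A `binned_track`, normally from [moving_average()].
#' @param fold_threshold Minimum height as a multiple of the genomic average
#'   (>= 1); the analyses here use 2 or 5.
#' @return Data frame with columns chrom, bin_index (0-based), center_pos,
#'   height, fold_over_mean, sorted in genome order.
#' @export
find_peaks <- function(smoothed, fold_threshold = 2) {
  stopifnot(inherits(smoothed, "binned_track"))
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  g <- genomic_average(smoothed)
  res <- lapply(names(smoothed$values), function(ch) {
    v <- smoothed$values[[ch]]
    idx <- local_maxima_runs(v)
    if (length(idx) == 0L) return(NULL)
    keep <- v[idx] >= fold_threshold * g
    idx <- idx[keep]
    if (length(idx) == 0L) return(NULL)
    data.frame(chrom = ch, bin_index = idx - 1L,
               center_pos = (idx - 1) * smoothed$bin_size + smoothed$bin_size / 2,
               height = v[idx],
               fold_over_mean = if (g > 0) v[idx] / g else Inf,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(), bin_index = integer(),
                      center_pos = numeric(), height = numeric(),
                      fold_over_mean = numeric(), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

# 1-based indices of strict local maxima, plateau runs collapsed to their
# midpoint bin (ties leftward); terminal runs need only beat their one neighbor
local_maxima_runs <- function(v) {
  n <- length(v)
  if (n == 0L) return(integer())
  if (n == 1L) return(integer())  # no neighbor to beat
  r <- rle(v)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- integer()
  for (k in seq_along(r$values)) {
    left_ok <- if (k == 1L) TRUE else r$values[k] > r$values[k - 1L]
    right_ok <- if (k == length(r$values)) TRUE else r$values[k] > r$values[k + 1L]
    if (k == 1L && k == length(r$values)) next  # constant chromosome
    if (left_ok && right_ok)
      out <- c(out, starts[k] + floor((r$lengths[k] - 1L) / 2))
  }
  out
}

#' Bins high in both SV and SNV signal
#'
#' Returns the bins where both tracks are at least `fold_threshold` times
#' their own genomic average — the loci analyzed for echoed induction.
#'
#' @param sv_track,snv_track `binned_track`s on the same assembly and
#'   bin size (normally smoothed).
#' @param fold_threshold Fold over each track's genomic average (default 2).
#' @return Data frame with columns chrom, bin_index (0-based).
#' @export
high_loci <- function(sv_track, snv_track, fold_threshold = 2) {
  stopifnot(inherits(sv_track, "binned_track"), inherits(snv_track, "binned_track"))
  if (!same_grid(sv_track, snv_track))
    stop("tracks must share assembly and bin_size")
  g_sv <- genomic_average(sv_track)
  g_snv <- genomic_average(snv_track)
  res <- lapply(names(sv_track$values), function(ch) {
    hit <- sv_track$values[[ch]] >= fold_threshold * g_sv &
      snv_track$values[[ch]] >= fold_threshold * g_snv
    if (!any(hit)) return(NULL)
    data.frame(chrom = ch, bin_index = which(hit) - 1L, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, res)
  if (is.null(res))
    res <- data.frame(chrom = character(), bin_index = integer(),
                      stringsAsFactors = FALSE)
  rownames(res) <- NULL
  res
}

#' Export a track as TSV
#'
#' Columns: chrom, bin_start, bin_end (0-based half-open, end clipped to the
#' chromosome), value.
#'
#' @param track A `binned_track`.
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  rows <- lapply(names(track$values), function(ch) {
    v <- track$values[[ch]]
    if (length(v) == 0L) return(NULL)
    start <- (seq_along(v) - 1) * track$bin_size
    data.frame(chrom = ch, bin_start = start,
               bin_end = pmin(start + track$bin_size,
                              track$assembly$length[[ch]]),
               value = v, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Rotate each chromosome's bins by an offset
#'
#' Circularly shifts the per-chromosome bin values. Used to build permutation
#' nulls for the echo analysis: rotation preserves each chromosome's value
#' multiset while destroying positional association with SV peaks.
#'
#' @param track A `binned_track`.
#' @param offsets Integer vector of per-chromosome bin shifts (recycled), or
#'   NULL to draw one uniform shift per chromosome from the current RNG state.
#' @return A rotated `binned_track`.
#' @export
rotate_track <- function(track, offsets = NULL) {
  stopifnot(inherits(track, "binned_track"))
  chs <- names(track$values)
  if (is.null(offsets)) {
    offsets <- vapply(chs, function(ch)
      sample.int(max(length(track$values[[ch]]), 1L), 1L), integer(1))
  }
  offsets <- rep_len(as.integer(offsets), length(chs))
  for (i in seq_along(chs)) {
    v <- track$values[[chs[i]]]
    n <- length(v)
    if (n < 2L) next
    k <- offsets[i] %% n
    if (k > 0L) track$values[[chs[i]]] <- c(v[(n - k + 1L):n], v[1:(n - k)])
  }
  track
}
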