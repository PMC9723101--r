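# Inter-SNV distances (rainfall data), kataegis cluster calling, SV-high/low
# bin classification, and the Welch comparison of inter-SNV distances between
# SV-high and SV-low regions.

#' Inter-SNV distances (rainfall points)
#'
#' For each SNV, the distance to the preceding SNV on the same chromosome
#' (undefined, NA, for the first per chromosome). Zones follow rainfall-plot
#' convention: `lt_1kb` (< 1 kb), `kb_1_to_Mb_1` (1 kb – 1 Mb), `ge_1Mb`.
#' Duplicate positions yield distance 0 and are flagged in `is_tie`.
#'
#' @param snvs An [snv_set()] (sorted by construction).
#' @return Data frame: chrom, pos, dist_to_prev, zone, is_tie.
#' @export
inter_snv_distances <- function(snvs) {
  stopifnot(inherits(snvs, "snv_set"))
  if (nrow(snvs) == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      dist_to_prev = numeric(), zone = character(),
                      is_tie = logical(), stringsAsFactors = FALSE))
  d <- c(NA_real_, diff(snvs$pos))
  first <- c(TRUE, snvs$chrom[-1L] != snvs$chrom[-nrow(snvs)])
  d[first] <- NA_real_
  zone <- rep(NA_character_, length(d))
  zone[!is.na(d) & d < 1000] <- "lt_1kb"
  zone[!is.na(d) & d >= 1000 & d < 1e6] <- "kb_1_to_Mb_1"
  zone[!is.na(d) & d >= 1e6] <- "ge_1Mb"
  data.frame(chrom = snvs$chrom, pos = snvs$pos, dist_to_prev = d,
             zone = zone, is_tie = !is.na(d) & d == 0,
             stringsAsFactors = FALSE)
}

#' Call kataegis clusters
#'
#' By the chain rule (default), a cluster is a maximal run of consecutive
#' same-chromosome SNVs in which every adjacent gap is at most `max_gap`;
#' runs with at least `min_count` members are reported, so a cluster may span
#' more than `max_gap` in total. The stricter `method = "window"` instead
#' requires at least `min_count` SNVs inside a single window of `max_gap`
#' base pairs, and reports maximal merged groups of window-supported SNVs.
#'
#' @param snvs An [snv_set()].
#' @param max_gap Maximum adjacent gap (chain) or window width (window), in
#'   base pairs; default 1000.
#' @param min_count Minimum SNVs per cluster; default 3.
#' @param method "chain" (default) or "window".
#' @return Data frame in genome order: chrom, start_pos, end_pos (positions of
#'   the first and last member SNV), n_snvs, max_gap.
#' @export
call_kataegis <- function(snvs, max_gap = 1000, min_count = 3L,
                          method = c("chain", "window")) {
  stopifnot(inherits(snvs, "snv_set"))
  method <- match.arg(method)
  if (max_gap < 1) stop("max_gap must be >= 1")
  if (min_count < 2) stop("min_count must be >= 2")
  empty <- data.frame(chrom = character(), start_pos = numeric(),
                      end_pos = numeric(), n_snvs = integer(),
                      max_gap = numeric(), stringsAsFactors = FALSE)
  if (nrow(snvs) == 0L) return(empty)
  res <- lapply(unique(snvs$chrom), function(ch) {
    p <- snvs$pos[snvs$chrom == ch]  # sorted
    member <- if (method == "chain") {
      chain_runs(p, max_gap)
    } else {
      window_members(p, max_gap, min_count)
    }
    if (is.null(member)) return(NULL)
    grp <- member$grp; keep_tab <- table(grp)
    ok <- names(keep_tab)[keep_tab >= min_count]
    if (length(ok) == 0L) return(NULL)
    do.call(rbind, lapply(ok, function(g) {
      q <- p[grp == g & !is.na(grp)]
      data.frame(chrom = ch, start_pos = min(q), end_pos = max(q),
                 n_snvs = length(q), max_gap = max_gap,
                 stringsAsFactors = FALSE)
    }))
  })
  res <- do.call(rbind, res)
  if (is.null(res)) return(empty)
  a <- assembly_of(snvs)
  res <- res[order(chrom_factor(res$chrom, a), res$start_pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# group ids of maximal runs with adjacent gaps <= max_gap
chain_runs <- function(p, max_gap) {
  if (length(p) == 0L) return(NULL)
  brk <- c(TRUE, diff(p) > max_gap)
  list(grp = cumsum(brk))
}

# window method: an SNV is supported if some max_gap-wide window holds
# >= min_count SNVs including it; supported SNVs closer than max_gap merge
window_members <- function(p, max_gap, min_count) {
  n <- length(p)
  if (n == 0L) return(NULL)
  supported <- rep(FALSE, n)
  j <- 1L
  for (i in seq_len(n)) {
    while (j <= n && p[j] <= p[i] + max_gap) j <- j + 1L
    if (j - i >= min_count) supported[i:(j - 1L)] <- TRUE
  }
  if (!any(supported)) return(NULL)
  grp <- rep(NA_integer_, n)
  ps <- p[supported]
  g <- cumsum(c(TRUE, diff(ps) > max_gap))
  grp[supported] <- g
  list(grp = grp)
}

#' Classify bins as SV-high or SV-low
#'
#' @param sv_smoothed A smoothed SV `binned_track`.
#' @param fold_threshold Bins at least this multiple of the genomic average
#'   are `sv_high`; others `sv_low`. Default 2.
#' @return Object of class `bin_labels`: a named list of per-chromosome
#'   character vectors, with assembly and bin_size attributes.
#' @export
classify_bins_by_sv <- function(sv_smoothed, fold_threshold = 2) {
  stopifnot(inherits(sv_smoothed, "binned_track"))
  if (fold_threshold < 1) stop("fold_threshold must be >= 1")
  g <- genomic_average(sv_smoothed)
  labels <- lapply(sv_smoothed$values, function(v)
    ifelse(v >= fold_threshold * g, "sv_high", "sv_low"))
  structure(labels, assembly = sv_smoothed$assembly,
            bin_size = sv_smoothed$bin_size, class = "bin_labels")
}

#' Compare inter-SNV distances between SV-high and SV-low regions
#'
#' Assigns each rainfall point to the bin containing its own position, splits
#' defined distances by the bin's label and runs Welch's two-tailed t test.
#' Distances are compared on the log10 scale by default (inter-mutation
#' distances are log-distributed; zero-distance ties are excluded there).
#'
#' @param points Output of [inter_snv_distances()].
#' @param labels Output of [classify_bins_by_sv()].
#' @param exclude_kataegis If TRUE, points falling inside `clusters` are
#'   dropped first.
#' @param clusters Output of [call_kataegis()]; required when
#'   `exclude_kataegis` is TRUE.
#' @param log_scale Compare log10 distances (default TRUE).
#' @return List: statistic, df, p_two_sided, n_high, n_low, mean_high,
#'   mean_low (means on the compared scale), log_scale, excluded_kataegis.
#' @export
compare_distances_by_region <- function(points, labels,
                                        exclude_kataegis = FALSE,
                                        clusters = NULL, log_scale = TRUE) {
  stopifnot(inherits(labels, "bin_labels"))
  bin_size <- attr(labels, "bin_size")
  pts <- points[!is.na(points$dist_to_prev), , drop = FALSE]
  if (exclude_kataegis) {
    if (is.null(clusters)) stop("exclude_kataegis requires clusters")
    drop <- rep(FALSE, nrow(pts))
    for (k in seq_len(nrow(clusters))) {
      drop <- drop | (pts$chrom == clusters$chrom[k] &
                        pts$pos >= clusters$start_pos[k] &
                        pts$pos <= clusters$end_pos[k])
    }
    pts <- pts[!drop, , drop = FALSE]
  }
  if (log_scale) pts <- pts[pts$dist_to_prev > 0, , drop = FALSE]
  lab <- character(nrow(pts))
  for (ch in unique(pts$chrom)) {
    sel <- pts$chrom == ch
    if (!ch %in% names(labels)) stop("chromosome absent from labels: ", ch)
    lab[sel] <- labels[[ch]][floor(pts$pos[sel] / bin_size) + 1L]
  }
  d <- if (log_scale) log10(pts$dist_to_prev) else pts$dist_to_prev
  hi <- d[lab == "sv_high"]; lo <- d[lab == "sv_low"]
  if (length(hi) < 2L || length(lo) < 2L)
    stop("need >= 2 defined distances in each region class")
  w <- welch_t_test(hi, lo)
  list(statistic = w$statistic, df = w$df, p_two_sided = w$p_two_sided,
       n_high = length(hi), n_low = length(lo),
       mean_high = mean(hi), mean_low = mean(lo),
       log_scale = log_scale, excluded_kataegis = exclude_kataegis)
}

#' Count SNVs by reference base-pair class
#'
#' Splits SNVs into those arising at A:T base pairs (reference A or T) and at
#' G:C base pairs (reference G or C).
#'
#' @param snvs An [snv_set()].
#' @return Named integer vector `c(AT = ..., GC = ...)`; the two always sum
#'   to the SNV total.
#' @export
stratify_by_base_pair <- function(snvs) {
  stopifnot(inherits(snvs, "snv_set"))
  c(AT = sum(snvs$ref %in% c("A", "T")),
    GC = sum(snvs$ref %in% c("G", "C")))
}
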