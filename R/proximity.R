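# Observed vs expected SNV counts near SV breakpoints, the random-expectation
# formula, per-sample enrichment summaries, the cohort-level test, and
# per-region SV/SNV tallies.

#' Random expectation of SV-proximal SNVs
#'
#' The number of SNVs expected within +/- `range_bp` of the SV sites if SNVs
#' were uniform over the genome:
#' `n_snv / genome_length * n_sv * 2 * range_bp`.
#' The formula is evaluated exactly as written — window overlaps are not
#' corrected; see [sample_enrichment()] for overlap-aware variants.
#'
#' @param n_snv Total SNV count in the sample.
#' @param genome_length Total assembly length in base pairs.
#' @param n_sv Number of SV sites (events by convention; see
#'   [sample_enrichment()]'s `sv_site_unit`).
#' @param range_bp Window half-width in base pairs (the analyses here use
#'   1 Mb and 100 kb).
#' @return Expected SNV count (may be non-integer).
#' @examples
#' expected_snv_count(3000, 3e9, 100, 1e6)  # 200
#' @export
expected_snv_count <- function(n_snv, genome_length, n_sv, range_bp) {
  if (any(genome_length <= 0)) stop("genome_length must be positive")
  if (any(n_snv < 0) || any(n_sv < 0) || any(range_bp < 0))
    stop("counts and range must be non-negative")
  n_snv / genome_length * n_sv * 2 * range_bp
}

# per-chromosome IRanges of +/- range_bp windows around all breakpoints,
# merged (reduced) and clipped to chromosome bounds; positions are 0-based
# inclusive so width() counts covered base positions
merged_breakpoint_windows <- function(svs, range_bp) {
  assembly <- assembly_of(svs)
  bp <- breakpoints(svs)
  out <- lapply(assembly$chrom, function(ch) {
    p <- bp$pos[bp$chrom == ch]
    if (length(p) == 0L) return(IRanges::IRanges())
    IRanges::reduce(IRanges::IRanges(
      start = pmax(p - range_bp, 0),
      end = pmin(p + range_bp, assembly$length[[ch]] - 1)))
  })
  names(out) <- assembly$chrom
  out
}

#' Count SNVs near SV breakpoints
#'
#' Counts distinct SNVs lying within +/- `range_bp` (boundary inclusive) of at
#' least one breakpoint of any SV on the same chromosome. Both breakpoints of
#' every SV are SV sites; an SNV covered by several windows is counted once.
#'
#' @param snvs An [snv_set()].
#' @param svs An [sv_set()] on the same assembly.
#' @param range_bp Window half-width in base pairs (>= 0).
#' @return Integer count.
#' @export
observed_snv_near_sv <- function(snvs, svs, range_bp) {
  stopifnot(inherits(snvs, "snv_set"), inherits(svs, "sv_set"))
  if (range_bp < 0) stop("range_bp must be >= 0")
  win <- merged_breakpoint_windows(svs, range_bp)
  total <- 0L
  for (ch in names(win)) {
    if (length(win[[ch]]) == 0L) next
    p <- snvs$pos[snvs$chrom == ch]
    if (length(p) == 0L) next
    q <- IRanges::IRanges(start = p, width = 1L)
    total <- total + sum(IRanges::countOverlaps(q, win[[ch]]) > 0L)
  }
  total
}

#' Relative SNV rate
#'
#' Observed SV-proximal SNV count over its random expectation.
#'
#' @param observed Observed count (>= 0).
#' @param expected Expected count (> 0).
#' @return `observed / expected`.
#' @export
relative_rate <- function(observed, expected) {
  if (any(expected <= 0)) stop("relative rate undefined: expected must be > 0")
  observed / expected
}

#' Per-sample SV-proximal SNV enrichment
#'
#' Computes, for one tumor, the observed number of SNVs within `range_bp` of
#' any SV breakpoint and three expectations:
#' \describe{
#'   \item{expected_near}{the literal random-expectation formula
#'     (density x n_sv x 2 x range), no overlap correction;}
#'   \item{expected_merged}{genome-wide SNV density times the merged window
#'     footprint (overlap-corrected);}
#'   \item{expected_bg}{background SNV density estimated outside the windows
#'     times the footprint — the expectation under no proximal induction.}
#' }
#' `relative_rate = observed / expected_near` reproduces the formula-based
#' rate; `fold_enrichment = observed / expected_bg` is a consistent estimator
#' of the true proximal rate elevation even when windows cover a sizable
#' genome fraction.
#'
#' @param snvs,svs Variant sets sharing an assembly.
#' @param range_bp Window half-width (default 1 Mb; 100 kb is the other scale
#'   used in these analyses).
#' @param sample_id Sample label carried into the result.
#' @param sv_site_unit "event" (default) uses the SV event count in the
#'   formula's `n_sv`; "breakpoint" uses the breakpoint count (twice the
#'   events), for sensitivity analysis.
#' @return One-row data frame: sample_id, range_bp, n_snv_total, n_sv_total,
#'   observed_near, expected_near, expected_merged, expected_bg, window_bp,
#'   relative_rate, fold_enrichment. Rates are NA when their denominator is 0.
#' @export
sample_enrichment <- function(snvs, svs, range_bp = 1e6, sample_id = "sample",
                              sv_site_unit = c("event", "breakpoint")) {
  sv_site_unit <- match.arg(sv_site_unit)
  assembly <- assembly_of(snvs)
  n_snv <- nrow(snvs)
  n_sv <- nrow(svs)
  n_sites <- if (sv_site_unit == "event") n_sv else 2L * n_sv
  G <- assembly$total_length
  obs <- observed_snv_near_sv(snvs, svs, range_bp)
  exp_near <- expected_snv_count(n_snv, G, n_sites, range_bp)
  win <- merged_breakpoint_windows(svs, range_bp)
  W <- sum(vapply(win, function(r) sum(IRanges::width(r)), numeric(1)))
  exp_merged <- n_snv / G * W
  exp_bg <- if (W > 0 && G > W) (n_snv - obs) / (G - W) * W else 0
  data.frame(
    sample_id = sample_id, range_bp = range_bp,
    n_snv_total = n_snv, n_sv_total = n_sv,
    observed_near = obs,
    expected_near = exp_near,
    expected_merged = exp_merged,
    expected_bg = exp_bg,
    window_bp = W,
    relative_rate = if (exp_near > 0) obs / exp_near else NA_real_,
    fold_enrichment = if (exp_bg > 0) obs / exp_bg else NA_real_,
    stringsAsFactors = FALSE)
}

#' Cohort-level test of SV-proximal SNV enrichment
#'
#' Tests whether observed SV-proximal SNV counts exceed expectation across
#' tumors. `paired_counts` runs a paired two-tailed t test of observed vs
#' expected per sample; `log_ratio` runs a one-sample two-tailed t test of
#' `log(observed / expected)` against 0.
#'
#' @param results Data frame of per-sample rows from [sample_enrichment()].
#' @param mode "paired_counts" (default) or "log_ratio".
#' @param expected Which expectation to test against: "eq1" (the literal
#'   formula, column expected_near), "merged", or "bg" (default "eq1").
#' @return List: mode, expected, statistic, df, p_value, n, mean_observed,
#'   mean_expected, degenerate (TRUE when the differences have zero variance;
#'   then p_value is exactly 1 if all differences are zero, NA otherwise).
#' @export
cohort_enrichment_test <- function(results,
                                   mode = c("paired_counts", "log_ratio"),
                                   expected = c("eq1", "merged", "bg")) {
  mode <- match.arg(mode)
  expected <- match.arg(expected)
  col <- switch(expected, eq1 = "expected_near", merged = "expected_merged",
                bg = "expected_bg")
  obs <- results$observed_near
  exp_ <- results[[col]]
  n <- length(obs)
  if (n < 3L) stop("cohort test needs at least 3 samples")
  base <- list(mode = mode, expected = expected, n = n,
               mean_observed = mean(obs), mean_expected = mean(exp_))
  if (mode == "paired_counts") {
    d <- obs - exp_
  } else {
    if (any(obs <= 0) || any(exp_ <= 0))
      stop("log_ratio mode requires positive observed and expected counts")
    d <- log(obs / exp_)
  }
  if (sd(d) == 0) {
    return(c(base, list(statistic = 0, df = n - 1L,
                        p_value = if (all(d == 0)) 1 else NA_real_,
                        degenerate = TRUE)))
  }
  tt <- t.test(d, mu = 0)
  c(base, list(statistic = unname(tt$statistic), df = unname(tt$parameter),
               p_value = tt$p.value, degenerate = FALSE))
}

#' SNV and SV-breakpoint tallies over named regions
#'
#' Counts, per region (e.g. gene), the SNVs and SV breakpoints it contains —
#' the substrate for plotting cases harboring both against SV burden.
#' Intervals are 0-based half-open; `flank_bp` extends each region
#' symmetrically (clipped to the chromosome) before counting, supporting
#' flanking-window analyses at 10 kb – 10 Mb scales.
#'
#' @param regions Data frame with columns name (or id), chrom, start, end.
#' @param snvs,svs Variant sets sharing an assembly.
#' @param flank_bp Symmetric extension in base pairs (default 0).
#' @return Data frame: region_id, chrom, start, end, n_snv, n_sv_breakpoints,
#'   has_both.
#' @export
region_tallies <- function(regions, snvs, svs, flank_bp = 0) {
  stopifnot(inherits(snvs, "snv_set"), inherits(svs, "sv_set"))
  assembly <- assembly_of(snvs)
  if (nrow(regions) == 0L)
    return(data.frame(region_id = character(), chrom = character(),
                      start = numeric(), end = numeric(), n_snv = integer(),
                      n_sv_breakpoints = integer(), has_both = logical(),
                      stringsAsFactors = FALSE))
  id_col <- if ("name" %in% names(regions)) "name" else "id"
  if (!id_col %in% names(regions)) stop("regions need a 'name' or 'id' column")
  if (any(regions$end <= regions$start)) stop("region end must exceed start")
  bp <- breakpoints(svs)
  start <- pmax(regions$start - flank_bp, 0)
  end <- pmin(regions$end + flank_bp, chrom_length(assembly, regions$chrom))
  n_snv <- integer(nrow(regions))
  n_bp <- integer(nrow(regions))
  for (i in seq_len(nrow(regions))) {
    ch <- regions$chrom[i]
    p <- snvs$pos[snvs$chrom == ch]
    n_snv[i] <- sum(p >= start[i] & p < end[i])
    q <- bp$pos[bp$chrom == ch]
    n_bp[i] <- sum(q >= start[i] & q < end[i])
  }
  data.frame(region_id = as.character(regions[[id_col]]),
             chrom = regions$chrom, start = start, end = end,
             n_snv = n_snv, n_sv_breakpoints = n_bp,
             has_both = n_snv > 0L & n_bp > 0L,
             stringsAsFactors = FALSE)
}
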