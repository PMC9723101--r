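---
title: "Methods: quantifying echoed SNV induction around SV breakpoints"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying echoed SNV induction around SV breakpoints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(svecho)
```

# The problem

In whole-genome sequenced tumors, somatic SNVs are not spread uniformly:
their density rises near structural variant breakpoints, SNV peaks shadow
SV peaks across megabase flanks, and kataegis — bursts of closely spaced
substitutions — preferentially nucleates near rearrangements. `svecho`
implements the analyses needed to quantify these effects in a cohort, plus
a ground-truth simulator so that every statistic is validated by parameter
recovery rather than by eye.

Coordinates are 0-based internally everywhere; VCF input/output is 1-based
on disk and BED/BEDPE 0-based half-open, with conversion confined to the
readers and writers. The breakpoint of each BEDPE mate interval is its
start coordinate: breakpoints are single positions, and taking the start is
deterministic across callers (this is our convention; SV call sets differ
and the choice is exposed, not hidden).

# Track machinery

SNVs and SV breakpoints are counted into fixed-width bins (default 1 Mb;
100 kb for fine-scale work) and smoothed with a centered moving average. A
"10 Mb" smoothing span over 1 Mb bins is realized as `span_bins = 11`
(the bin of interest ± 5 Mb): an odd, centered window keeps a smoothed peak
aligned with its cause, whereas a trailing window would shift every peak
downstream by half a span. At chromosome ends the window is truncated to
in-bounds bins and the mean divides by the truncated size; zero-padding
would fabricate depletion at telomeres.

Peaks are strict local maxima of the smoothed track that also clear a
fold-over-genomic-average threshold (2× by default, 5× as the stricter
alternative). We read "local maximum inflection point" as a strict local
maximum; no second-derivative analysis is performed. Plateaus of equal
values return their midpoint bin, ties broken leftward — an arbitrary but
deterministic rule. The genomic average includes zero-count bins
(centromeres, unmappable regions) by default because the uniform
expectation below makes the same choice; an exclusion mask (BED) is
accepted where the user wants the corrected baseline, and the two must be
used consistently.

# Proximal enrichment

For one tumor with `n` SNVs and `m` SV events on a genome of length `G`,
the expected number of SNVs within ± `Range` of the SV sites under
uniformity is

```
Expected = n / G × m × 2 × Range
```

evaluated exactly as written (`expected_snv_count()`), with no correction
for overlapping windows. The observed count (`observed_snv_near_sv()`) is
the number of *distinct* SNVs within `Range` (boundary inclusive) of at
least one breakpoint, both breakpoints of every SV counting as sites.
`relative_rate` is observed over this formula expectation.

The formula and the observed count are not exactly commensurate: the
formula charges each SV event one ± `Range` footprint, while the observed
count uses both breakpoints with implicit merging of overlaps. Whether `m`
should count events or breakpoints is ambiguous in practice, so
`sample_enrichment()` exposes `sv_site_unit = "event"` (default, the
conservative literal reading) or `"breakpoint"`. It also reports two
overlap-aware expectations computed from the *merged* window footprint `W`:

* `expected_merged = n / G × W` — genome-wide density times footprint;
* `expected_bg = (n − observed) / (G − W) × W` — background density
  estimated *outside* the windows, times footprint.

`fold_enrichment = observed / expected_bg` is the ratio of in-window to
out-of-window SNV density and is a consistent estimator of a true
multiplicative rate elevation `f` even when windows cover a sizable genome
fraction (at desk scale — 20 SVs with 1 Mb windows on a 150 Mb genome —
they cover ~20%, where the genome-wide-density variants are visibly biased
toward 1). Recovery tests therefore assert on `fold_enrichment`; the
formula-based `relative_rate` is always reported alongside for fidelity.

Cohort significance (`cohort_enrichment_test()`) is a paired two-tailed t
test of observed vs expected per tumor, or a one-sample t test of
`log(observed/expected)` against 0. Whether the original cohort analyses
paired per-tumor values or tested pooled expectations is not stated in our
sources; both modes are provided, with paired as default. Zero-variance
differences are reported as a degenerate flag (p = 1 when all differences
are zero) rather than an error, since all-zero cohorts are a legitimate
edge case. p values are raw; no multiple-testing correction is applied
anywhere.

# Kataegis and rainfall statistics

`inter_snv_distances()` computes, per chromosome, each SNV's distance to
its predecessor, with the rainfall zones < 1 kb, 1 kb–1 Mb and ≥ 1 Mb.
Duplicate positions give distance 0, are flagged, and are excluded from
log-scale tests (log undefined; duplicates usually reflect caller
artifacts).

"Three mutations within 1 kb or more" admits two readings. The default
chain rule calls a cluster when ≥ `min_count` (3) consecutive SNVs each lie
within `max_gap` (1 kb) of the previous one, so a cluster may span several
kb — this matches common rainfall-plot practice where kataegis appears as a
run of low inter-mutation distances. The strict alternative
(`method = "window"`) requires ≥ 3 SNVs inside a single 1 kb window. Both
are implemented and tested; neither is asserted to be the original
definition.

`compare_distances_by_region()` labels each rainfall point by the SV
status (`sv_high` / `sv_low`, ≥ 2× the genomic average on the smoothed SV
track) of the bin containing *its own position* (not the gap midpoint —
simpler and deterministic), then runs Welch's two-tailed t test on log10
distances. Inter-mutation distances are roughly log-distributed and
rainfall plots are drawn on a log axis, so the log scale is the default; a
raw-scale flag exists. Kataegis points can be excluded first, to show that
shorter distances in SV-high regions are not driven by kataegis alone.

# Echo profiles

`echo_profile()` extracts the smoothed SNV values at bin offsets
−`flank`..+`flank` (default ± 15 Mb) around every qualifying SV peak and
averages them across peaks per offset. Offsets falling off a chromosome are
skipped — each offset's mean divides by its own number of in-bounds
contributions. Peaks align at bin centers; no sub-bin interpolation is
attempted since the 1 Mb bin already bounds the resolution.

The superimposed profile is summarized by `echo_enrichment_score()`: the
profile mean within ± 1 Mb of the peak (one bin at the default grid, the
scale at which proximal enrichment is quantified) divided by the SNV
genomic average. The score is 1 under no association, exceeds 1 when SNV
density is elevated at SV peaks, and is invariant under uniform scaling of
the SNV track. This scalar is this package's quantification of the echo;
the source analyses present superimpositions and alignment densities
without defining one. Its null is established empirically: rotating each
chromosome's SNV bins by a random circular offset preserves the value
multiset while destroying positional association, and the score
distribution over rotations centers on 1.

# The synthetic cohort generator

`sim_config()` defaults define the study condition used throughout the
tests: 3 chromosomes × 50 Mb, 20 tumors, background 1e-5 SNVs/bp
(≈ 1 500 background SNVs per tumor), Poisson-20 SV events per tumor with
70% of first breakpoints in 5 shared 2 Mb hotspots, intra-chromosomal SV
sizes uniform on 1–100 kb with uniform classes (translocations forced
inter-chromosomal), a 3-fold SNV-rate elevation within 1 Mb of any
breakpoint, kataegis bursts of 8 SNVs (gaps uniform on 1–1 000 bp) at 10%
of breakpoints, 55% of SNVs at A:T pairs, and ages uniform on 30–80 years
with clock-like SNVs `500 + 25 × age + N(0, 100)`. The desk scale keeps
the full suite within minutes; a human-scale assembly is a `chrom_lengths`
argument away.

Two design points matter for correctness:

* **Exact enrichment by superposition.** Proximal SNVs are an independent
  Poisson process at `(f − 1)` times the realized uniform density,
  restricted to the *merged* ± d windows. The marginal in-window rate is
  therefore exactly `f` times the out-of-window rate even where windows
  overlap, and the elevation applies to the whole uniform process
  (background plus clock-like), as a local mutagenic effect should. A
  linear-taper variant (triangular kernel per breakpoint, additive under
  overlap, approximate rather than exact) is available via
  `enrichment_decay = "linear"`.
* **Per-sample seed streams.** Sample `i` of a cohort is generated under a
  seed derived from `(master_seed, i)`, so any sample is reproducible
  independently and in parallel, and identical invocations are
  byte-identical on disk.

The truth record per sample partitions SNVs into background, clock-like,
proximal and kataegis counts and stores planted cluster coordinates, so
recovery tests have exact ground truth. Null cohorts for test-size
calibration use `enrichment_fold = 1` *and* `kataegis_prob = 0`: kataegis
near breakpoints is itself real proximal induction, and leaving it on
would make the "null" genuinely non-null.

What the generator does **not** emulate: trinucleotide (96-channel)
sequence context, chromatin- or replication-timing-dependent regional
rates, subclonal structure, copy-number states, and caller artifacts.
Passing recovery tests therefore demonstrates correctness of the
statistics under the stated stochastic model, not robustness to every
feature of real tumor data — on real cohorts the exclusion mask and the
overlap-aware expectations are the main guards.

# Numerical and degenerate-input choices

* Distance comparisons at window boundaries are inclusive
  (`|snv − breakpoint| ≤ Range`).
* `bin_counts` assigns position `p` to bin `floor(p / bin_size)`; totals
  are conserved exactly, and rebinning consistency (ten 100 kb bins sum to
  the 1 Mb bin) is tested.
* Empty inputs return empty, typed results (empty VCF → empty SNV set;
  zero SVs → zero expectations with `NA` rates; no qualifying peaks → an
  explicit empty profile), never errors, except where a statistic is
  mathematically undefined (relative rate with zero expectation, Welch
  with a group of < 2, correlation of constants).
* Formula-level agreement between implementation and independent textbook
  oracles is asserted at 1e-9; Monte-Carlo recovery bands are set from the
  generating parameters, not tuned.
* The cohort for the statistics' null-size checks uses 2 000 replicates;
  the enrichment-test size check uses 200 simulated cohorts. Problem sizes
  throughout (desk-scale genome, 20-sample cohorts) were chosen once as
  the study condition.

# Known limitations

* The Fisher r-to-z comparison treats the two correlations as independent;
  when both involve a shared variable (e.g. SNV burden vs SV burden and
  SNV burden vs age), the proper dependent-correlation test (Steiger's)
  would differ. The literal z test is implemented because it is the stated
  method of the analyses being reproduced; results carry an
  `independence_assumed` flag.
* Peak calling has no false-discovery control; thresholds are fold-based,
  matching the source analyses.
* The VCF writer emits the minimal 8 fixed columns only; FORMAT/genotype
  data are out of scope, as are variant calling, annotation, and
  signature decomposition itself (signature *counts* are consumed, via the
  clock-like normalization).
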