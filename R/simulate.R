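# Synthetic tumor cohorts with known ground truth. The generator reproduces
# the statistical structure the analyses assume: hotspot-clustered SV
# breakpoints, homogeneous Poisson background SNVs, a multiplicative SNV-rate
# elevation within a fixed distance of any breakpoint (implemented by
# superposition on the merged windows, so the marginal rate is exact even
# where windows overlap), optional kataegis bursts near breakpoints, an A:T
# vs G:C reference-base mixture, and an age-linked clock-like SNV subset.

#' Simulation configuration
#'
#' Defaults describe a desk-scale study condition: three 50 Mb chromosomes,
#' 20 tumors, a background rate of 1e-5 SNVs per bp, a Poisson mean of 20 SVs
#' per tumor with 70% of breakpoints falling in 5 shared 2 Mb hotspots,
#' 3-fold SNV elevation within 1 Mb of any breakpoint, kataegis bursts of 8
#' SNVs at 10% of breakpoints, 55% of SNVs at A:T pairs, and a clock-like
#' subset growing linearly with age (uniform 30–80 years). A human-scale
#' assembly can be supplied via `chrom_lengths`.
#'
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param n_samples Number of tumors in a cohort.
#' @param sv_mean Poisson mean of SV events per tumor.
#' @param n_hotspots,hotspot_width,hotspot_fraction Shared SV hotspots: count,
#'   width (bp), and the fraction of first breakpoints drawn inside one.
#' @param sv_size_min,sv_size_max Intra-chromosomal SV size range (bp).
#' @param lambda_bg Background SNV rate per base pair.
#' @param enrichment_fold Multiplicative SNV-rate elevation `f >= 1` within
#'   `enrichment_range` of any breakpoint.
#' @param enrichment_range Enrichment distance `d` in bp (default 1 Mb).
#' @param enrichment_decay "step" (flat elevation across the window, exact by
#'   superposition) or "linear" (triangular taper to the background at
#'   distance d; overlapping windows then superpose additively).
#' @param kataegis_prob Probability a breakpoint nucleates a kataegis burst.
#' @param kataegis_size SNVs per burst.
#' @param kataegis_gap_max Intra-burst gaps drawn uniformly on
#'   `[1, kataegis_gap_max]` bp.
#' @param at_fraction Fraction of SNVs with reference base A or T.
#' @param age_model List: enabled, min, max (years), alpha, beta (clock-like
#'   SNVs = alpha + beta * age + normal noise of sd `sd`, floored at 0).
#' @param seed Master seed; per-sample streams are derived from
#'   (seed, sample_index) so samples are independently reproducible.
#' @return Object of class `sim_config` (a validated list, with hotspot
#'   centers drawn deterministically from the master seed).
#' @export
sim_config <- function(chrom_lengths = c(chrA = 5e7, chrB = 5e7, chrC = 5e7),
                       n_samples = 20L,
                       sv_mean = 20,
                       n_hotspots = 5L,
                       hotspot_width = 2e6,
                       hotspot_fraction = 0.7,
                       sv_size_min = 1e3,
                       sv_size_max = 1e5,
                       lambda_bg = 1e-5,
                       enrichment_fold = 3,
                       enrichment_range = 1e6,
                       enrichment_decay = c("step", "linear"),
                       kataegis_prob = 0.1,
                       kataegis_size = 8L,
                       kataegis_gap_max = 1000,
                       at_fraction = 0.55,
                       age_model = list(enabled = TRUE, min = 30, max = 80,
                                        alpha = 500, beta = 25, sd = 100),
                       seed = 1L) {
  enrichment_decay <- match.arg(enrichment_decay)
  assembly <- genome_assembly(names(chrom_lengths), unname(chrom_lengths))
  stopifnot(n_samples >= 0, sv_mean >= 0, n_hotspots >= 0,
            hotspot_width > 0, hotspot_fraction >= 0, hotspot_fraction <= 1,
            sv_size_min >= 1, sv_size_max >= sv_size_min,
            lambda_bg >= 0, enrichment_fold >= 1,
            kataegis_prob >= 0, kataegis_prob <= 1,
            kataegis_size >= 2, kataegis_gap_max >= 1,
            at_fraction >= 0, at_fraction <= 1)
  if (enrichment_range > min(assembly$length))
    stop("enrichment_range must not exceed the shortest chromosome")
  seed <- as.integer(seed)
  cfg <- list(assembly = assembly, n_samples = as.integer(n_samples),
              sv_mean = sv_mean, n_hotspots = as.integer(n_hotspots),
              hotspot_width = hotspot_width,
              hotspot_fraction = hotspot_fraction,
              sv_size_min = sv_size_min, sv_size_max = sv_size_max,
              lambda_bg = lambda_bg, enrichment_fold = enrichment_fold,
              enrichment_range = enrichment_range,
              enrichment_decay = enrichment_decay,
              kataegis_prob = kataegis_prob,
              kataegis_size = as.integer(kataegis_size),
              kataegis_gap_max = kataegis_gap_max,
              at_fraction = at_fraction, age_model = age_model, seed = seed)
  cfg$hotspots <- with_seed(derive_seed(seed, 0L), draw_hotspots(cfg))
  structure(cfg, class = "sim_config")
}

# deterministic per-sample seed stream; kept inside 32-bit integer range
derive_seed <- function(master, index) {
  as.integer((as.numeric(master) * 48271 + as.numeric(index) * 16807 + 11) %%
               2147483629)
}

# run expr under a temporary seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

draw_hotspots <- function(cfg) {
  if (cfg$n_hotspots == 0L)
    return(data.frame(chrom = character(), center = numeric(),
                      stringsAsFactors = FALSE))
  a <- cfg$assembly
  half <- cfg$hotspot_width / 2
  chrom <- sample(a$chrom, cfg$n_hotspots, replace = TRUE,
                  prob = unname(a$length))
  center <- vapply(chrom, function(ch)
    floor(runif(1, half, a$length[[ch]] - half)), numeric(1))
  data.frame(chrom = chrom, center = unname(center), stringsAsFactors = FALSE)
}

uniform_genome_positions <- function(n, assembly) {
  if (n == 0L)
    return(data.frame(chrom = character(), pos = numeric(),
                      stringsAsFactors = FALSE))
  chrom <- sample(assembly$chrom, n, replace = TRUE,
                  prob = unname(assembly$length))
  pos <- floor(runif(n) * chrom_length(assembly, chrom))
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

#' Simulate one tumor sample
#'
#' Deterministic given `(config$seed, sample_index)`: the same pair always
#' yields the same variants, byte for byte once written.
#'
#' @param config A [sim_config()].
#' @param sample_index 1-based sample number.
#' @return List: `snvs` ([snv_set()]), `svs` ([sv_set()]), and `truth` — a
#'   list holding the sample's age, clock-like count, SNV class counts
#'   (background / clock / proximal / kataegis), planted kataegis cluster
#'   coordinates, and the generating parameters.
#' @export
simulate_sample <- function(config, sample_index) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(derive_seed(config$seed, as.integer(sample_index)),
            simulate_sample_impl(config, sample_index))
}

simulate_sample_impl <- function(cfg, sample_index) {
  a <- cfg$assembly
  sample_id <- sprintf("S%03d", sample_index)

  ## age and clock-like burden
  am <- cfg$age_model
  age <- if (isTRUE(am$enabled)) runif(1, am$min, am$max) else NA_real_
  n_clock <- if (isTRUE(am$enabled))
    max(0L, as.integer(round(am$alpha + am$beta * age + rnorm(1, 0, am$sd))))
  else 0L

  ## SV events
  n_sv <- rpois(1, cfg$sv_mean)
  svs <- draw_svs(cfg, n_sv)

  ## background + clock-like SNVs (both uniform over the genome)
  n_bg <- rpois(length(a$chrom), cfg$lambda_bg * unname(a$length))
  bg <- do.call(rbind, lapply(seq_along(a$chrom), function(i) {
    data.frame(chrom = rep(a$chrom[i], n_bg[i]),
               pos = floor(runif(n_bg[i]) * a$length[[i]]),
               stringsAsFactors = FALSE)
  }))
  clock <- uniform_genome_positions(n_clock, a)

  ## proximal SNVs: superposed process at (f-1) times the realized uniform
  ## density on the merged windows, so the in/out density ratio is exactly f
  uniform_density <- (sum(n_bg) + n_clock) / a$total_length
  prox <- draw_proximal(cfg, svs, uniform_density)

  ## kataegis bursts near breakpoints
  kat <- draw_kataegis(cfg, svs)

  all_pos <- rbind(bg, clock, prox$positions, kat$positions)
  n_total <- nrow(all_pos)
  is_at <- runif(n_total) < cfg$at_fraction
  ref <- ifelse(is_at, sample(c("A", "T"), n_total, replace = TRUE),
                sample(c("G", "C"), n_total, replace = TRUE))
  # alt drawn uniformly over the three non-reference bases
  others <- t(vapply(BASES, function(b) setdiff(BASES, b), character(3)))
  alt <- others[cbind(match(ref, BASES),
                      sample.int(3L, n_total, replace = TRUE))]
  if (is.null(alt)) alt <- character()
  snvs <- snv_set(all_pos$chrom, all_pos$pos, ref, alt, a)

  truth <- list(sample_id = sample_id, age = age,
                clock_like_count = n_clock,
                n_background = sum(n_bg), n_clock = n_clock,
                n_proximal = nrow(prox$positions),
                n_kataegis = nrow(kat$positions),
                n_total = n_total, n_sv = n_sv,
                enrichment_fold = cfg$enrichment_fold,
                enrichment_range = cfg$enrichment_range,
                kataegis_clusters = kat$clusters,
                hotspots = cfg$hotspots)
  list(snvs = snvs, svs = svs, truth = truth, sample_id = sample_id)
}

draw_svs <- function(cfg, n_sv) {
  a <- cfg$assembly
  if (n_sv == 0L) return(sv_set(assembly = a))
  half <- cfg$hotspot_width / 2
  chrom1 <- character(n_sv); pos1 <- numeric(n_sv)
  in_hot <- cfg$n_hotspots > 0L & runif(n_sv) < cfg$hotspot_fraction
  for (i in seq_len(n_sv)) {
    if (in_hot[i]) {
      h <- cfg$hotspots[sample.int(nrow(cfg$hotspots), 1L), ]
      chrom1[i] <- h$chrom
      pos1[i] <- floor(runif(1, max(0, h$center - half),
                             min(a$length[[h$chrom]], h$center + half)))
    } else {
      u <- uniform_genome_positions(1L, a)
      chrom1[i] <- u$chrom; pos1[i] <- u$pos
    }
  }
  cls <- sample(c("duplication", "inversion", "deletion", "translocation"),
                n_sv, replace = TRUE)
  chrom2 <- chrom1; pos2 <- numeric(n_sv)
  for (i in seq_len(n_sv)) {
    if (cls[i] == "translocation" && length(a$chrom) > 1L) {
      chrom2[i] <- sample(setdiff(a$chrom, chrom1[i]), 1L)
      pos2[i] <- floor(runif(1) * a$length[[chrom2[i]]])
    } else {
      if (cls[i] == "translocation") cls[i] <- "inversion"  # single-chromosome assembly
      size <- floor(runif(1, cfg$sv_size_min, cfg$sv_size_max + 1))
      L <- a$length[[chrom1[i]]]
      pos2[i] <- if (pos1[i] + size < L) pos1[i] + size else max(pos1[i] - size, 0)
    }
  }
  sv_set(chrom1, pos1, chrom2, pos2, cls, a)
}

draw_proximal <- function(cfg, svs, uniform_density) {
  a <- cfg$assembly
  empty <- data.frame(chrom = character(), pos = numeric(),
                      stringsAsFactors = FALSE)
  extra <- (cfg$enrichment_fold - 1) * uniform_density
  if (nrow(svs) == 0L || extra <= 0) return(list(positions = empty))
  if (cfg$enrichment_decay == "step") {
    win <- merged_breakpoint_windows(svs, cfg$enrichment_range)
    widths <- lapply(win, IRanges::width)
    W <- sum(unlist(widths, use.names = FALSE))
    n <- rpois(1, extra * W)
    if (n == 0L) return(list(positions = empty))
    # choose a window interval weighted by width, then uniform inside it
    flat <- do.call(rbind, lapply(names(win), function(ch) {
      if (length(win[[ch]]) == 0L) return(NULL)
      data.frame(chrom = ch, start = IRanges::start(win[[ch]]),
                 width = IRanges::width(win[[ch]]), stringsAsFactors = FALSE)
    }))
    k <- sample.int(nrow(flat), n, replace = TRUE, prob = flat$width)
    pos <- flat$start[k] + floor(runif(n) * flat$width[k])
    return(list(positions = data.frame(chrom = flat$chrom[k], pos = pos,
                                       stringsAsFactors = FALSE)))
  }
  # linear taper: triangular kernel of mass d per breakpoint, additive overlap
  bp <- breakpoints(svs)
  d <- cfg$enrichment_range
  n <- rpois(1, extra * d * nrow(bp))
  if (n == 0L) return(list(positions = empty))
  k <- sample.int(nrow(bp), n, replace = TRUE)
  off <- round(d * (runif(n) + runif(n) - 1))
  pos <- pmin(pmax(bp$pos[k] + off, 0), chrom_length(a, bp$chrom[k]) - 1)
  list(positions = data.frame(chrom = bp$chrom[k], pos = pos,
                              stringsAsFactors = FALSE))
}

draw_kataegis <- function(cfg, svs) {
  a <- cfg$assembly
  empty_pos <- data.frame(chrom = character(), pos = numeric(),
                          stringsAsFactors = FALSE)
  empty_cl <- data.frame(chrom = character(), start_pos = numeric(),
                         end_pos = numeric(), n_snvs = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(svs) == 0L || cfg$kataegis_prob <= 0)
    return(list(positions = empty_pos, clusters = empty_cl))
  bp <- breakpoints(svs)
  hit <- runif(nrow(bp)) < cfg$kataegis_prob
  pos_list <- list(); cl_list <- list()
  for (i in which(hit)) {
    L <- chrom_length(a, bp$chrom[i])
    gaps <- floor(runif(cfg$kataegis_size - 1L, 1, cfg$kataegis_gap_max + 1))
    span <- sum(gaps)
    start <- bp$pos[i] + round(runif(1, -1e4, 1e4))
    start <- min(max(start, 0), L - 1 - span)
    if (start < 0) next  # chromosome shorter than the burst; skip
    p <- start + c(0, cumsum(gaps))
    pos_list[[length(pos_list) + 1L]] <-
      data.frame(chrom = bp$chrom[i], pos = p, stringsAsFactors = FALSE)
    cl_list[[length(cl_list) + 1L]] <-
      data.frame(chrom = bp$chrom[i], start_pos = min(p), end_pos = max(p),
                 n_snvs = length(p), stringsAsFactors = FALSE)
  }
  if (length(pos_list) == 0L)
    return(list(positions = empty_pos, clusters = empty_cl))
  list(positions = do.call(rbind, pos_list),
       clusters = do.call(rbind, cl_list))
}

#' Simulate a cohort, optionally writing it to disk
#'
#' @param config A [sim_config()].
#' @param out_dir If non-NULL, per-sample VCF and BEDPE files, a metadata TSV
#'   (sample_id, age, SBS1, SBS5, SBS_other), a truth JSON and a manifest
#'   JSON (file list plus the configuration echo and its hash) are written
#'   there.
#' @return List: `samples` (per-sample lists from [simulate_sample()]),
#'   `meta` (data frame), `truth` (per-sample truth records), `config`, and
#'   `manifest` (when written).
#' @export
simulate_cohort <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  samples <- lapply(seq_len(config$n_samples),
                    function(i) simulate_sample(config, i))
  meta <- do.call(rbind, lapply(samples, function(s) {
    clock <- s$truth$clock_like_count
    data.frame(sample_id = s$sample_id, age = s$truth$age,
               SBS1 = floor(clock / 2), SBS5 = ceiling(clock / 2),
               SBS_other = s$truth$n_total - clock,
               stringsAsFactors = FALSE)
  }))
  if (is.null(meta)) meta <- data.frame(sample_id = character(),
                                        age = numeric(), SBS1 = numeric(),
                                        SBS5 = numeric(), SBS_other = numeric())
  out <- list(samples = samples, meta = meta,
              truth = lapply(samples, `[[`, "truth"), config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (s in samples) {
      vcf <- file.path(out_dir, paste0(s$sample_id, ".vcf"))
      bedpe <- file.path(out_dir, paste0(s$sample_id, ".bedpe"))
      write_snv_subset(s$snvs, vcf)
      write_svs_bedpe(s$svs, bedpe)
      files[[s$sample_id]] <- list(vcf = basename(vcf), bedpe = basename(bedpe))
    }
    meta_path <- file.path(out_dir, "metadata.tsv")
    write.table(meta, meta_path, sep = "\t", quote = FALSE, row.names = FALSE)
    truth_path <- file.path(out_dir, "truth.json")
    jsonlite::write_json(out$truth, truth_path, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    cfg_echo <- config_echo(config)
    manifest <- list(samples = files, metadata = basename(meta_path),
                     truth = basename(truth_path), config = cfg_echo,
                     config_hash = config_hash(cfg_echo))
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    out$manifest <- manifest
  }
  out
}

# plain-list rendering of a config for manifests
config_echo <- function(config) {
  cfg <- unclass(config)
  cfg$assembly <- as.list(setNames(unname(cfg$assembly$length),
                                   cfg$assembly$chrom))
  cfg$hotspots <- NULL
  cfg
}

config_hash <- function(x) {
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), tf)
  unname(tools::md5sum(tf))
}
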