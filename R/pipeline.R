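# Orchestration: one entry point running each analysis stage end to end on a
# cohort directory (as produced by the simulator: per-sample VCF + BEDPE,
# chrom.sizes, metadata.tsv, manifest.json), with every threshold a
# configurable default and a config echo + hash in every output manifest.
# Results go to files; logging goes to stderr.

#' Pipeline run configuration
#'
#' Defaults mirror the analysis scales used throughout: 1 Mb bins smoothed
#' over an 11-bin (+/- 5 Mb) window, 1 Mb proximity range, 2-fold peak
#' threshold (5-fold as the stricter alternative), +/- 15 Mb echo flanks, and
#' kataegis as >= 3 SNVs with adjacent gaps <= 1 kb.
#'
#' @param cohort_dir Directory holding the cohort (see [simulate_cohort()]).
#' @param out_dir Output directory (default `cohort_dir`).
#' @param bin_size,span_bins,range_bp,fold_threshold,flank_bp,
#'   kataegis_max_gap,kataegis_min_count Analysis parameters.
#' @param seed Seed for any stage using randomness.
#' @param sim A [sim_config()] for the simulate stage (default one is built
#'   from `seed`).
#' @param regions Optional path to a named-region BED for the tallies stage.
#' @param config_file Optional YAML file; its entries override the defaults,
#'   and explicit arguments override the file.
#' @param ... Additional overrides stored verbatim.
#' @return Object of class `run_config`.
#' @export
run_config <- function(cohort_dir = NULL, out_dir = NULL,
                       bin_size = 1e6, span_bins = 11L, range_bp = 1e6,
                       fold_threshold = 2, flank_bp = 15e6,
                       kataegis_max_gap = 1000, kataegis_min_count = 3L,
                       seed = 1L, sim = NULL, regions = NULL,
                       config_file = NULL, ...) {
  cfg <- list(cohort_dir = cohort_dir, out_dir = out_dir,
              bin_size = bin_size, span_bins = span_bins,
              range_bp = range_bp, fold_threshold = fold_threshold,
              flank_bp = flank_bp, kataegis_max_gap = kataegis_max_gap,
              kataegis_min_count = kataegis_min_count, seed = as.integer(seed),
              sim = sim, regions = regions, ...)
  if (!is.null(config_file)) {
    file_cfg <- yaml::read_yaml(config_file)
    supplied <- names(as.list(match.call())[-1])
    for (k in setdiff(names(file_cfg), supplied)) cfg[[k]] <- file_cfg[[k]]
  }
  if (is.null(cfg$out_dir)) cfg$out_dir <- cfg$cohort_dir
  stopifnot(cfg$bin_size >= 1, cfg$span_bins %% 2 == 1,
            cfg$range_bp >= 0, cfg$fold_threshold >= 1,
            cfg$flank_bp %% cfg$bin_size == 0)
  structure(cfg, class = "run_config")
}

pipeline_log <- function(...) message("[svecho] ", sprintf(...))

#' Run a pipeline stage
#'
#' Stages: `simulate` (write a synthetic cohort), `enrich` (per-sample
#' observed-vs-expected proximity enrichment + cohort test), `kataegis`
#' (per-sample rainfall TSV, cluster BED and SV-high/low Welch comparison),
#' `echo` (cohort-pooled SV-peak echo profile and score), `correlate`
#' (cohort SNV–SV and SNV–age correlations, their Fisher comparison, and
#' AT/GC-stratified regression slopes), `tallies` (per-region SV/SNV
#' co-occurrence), `report` (merge the stage JSONs).
#'
#' @param subcommand One of simulate, enrich, kataegis, echo, correlate,
#'   tallies, report.
#' @param config A [run_config()].
#' @return Invisibly, the stage's main result object; files are written under
#'   `config$out_dir`, each run adding a manifest entry with the config hash.
#' @export
run_pipeline <- function(subcommand = c("simulate", "enrich", "kataegis",
                                        "echo", "correlate", "tallies",
                                        "report"),
                         config = run_config()) {
  subcommand <- match.arg(subcommand)
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  if (is.null(config$out_dir)) stop("out_dir (or cohort_dir) is required")
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- switch(subcommand,
                simulate = stage_simulate(config),
                enrich = stage_enrich(config),
                kataegis = stage_kataegis(config),
                echo = stage_echo(config),
                correlate = stage_correlate(config),
                tallies = stage_tallies(config),
                report = stage_report(config))
  record_manifest(config, subcommand)
  invisible(res)
}

record_manifest <- function(config, subcommand) {
  echo <- unclass(config)
  echo$sim <- if (!is.null(config$sim)) config_echo(config$sim) else NULL
  entry <- list(subcommand = subcommand, config = echo,
                config_hash = config_hash(echo))
  path <- file.path(config$out_dir, "run_manifest.json")
  existing <- if (file.exists(path))
    jsonlite::read_json(path, simplifyVector = FALSE) else list()
  existing[[subcommand]] <- entry
  jsonlite::write_json(existing, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

stage_simulate <- function(config) {
  sim <- config$sim
  if (is.null(sim)) sim <- sim_config(seed = config$seed)
  pipeline_log("simulating %d sample(s) into %s", sim$n_samples,
               config$out_dir)
  cohort <- simulate_cohort(sim, config$out_dir)
  sizes <- file.path(config$out_dir, "chrom.sizes")
  writeLines(sprintf("%s\t%.0f", sim$assembly$chrom,
                     unname(sim$assembly$length)), sizes)
  cohort
}

# read a cohort directory back through the package's own parsers
load_cohort <- function(config) {
  dir <- config$cohort_dir
  if (is.null(dir)) stop("cohort_dir is required for this stage")
  assembly <- read_chrom_sizes(file.path(dir, "chrom.sizes"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = FALSE)
  meta <- read.table(file.path(dir, "metadata.tsv"), header = TRUE,
                     sep = "\t", stringsAsFactors = FALSE)
  samples <- lapply(names(manifest$samples), function(sid) {
    list(sample_id = sid,
         snvs = read_snvs(file.path(dir, manifest$samples[[sid]]$vcf),
                          assembly),
         svs = read_svs(file.path(dir, manifest$samples[[sid]]$bedpe),
                        assembly))
  })
  list(assembly = assembly, samples = samples, meta = meta)
}

stage_enrich <- function(config) {
  co <- load_cohort(config)
  rows <- do.call(rbind, lapply(co$samples, function(s)
    sample_enrichment(s$snvs, s$svs, range_bp = config$range_bp,
                      sample_id = s$sample_id)))
  write.table(rows, file.path(config$out_dir, "enrichment.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  test <- tryCatch(cohort_enrichment_test(rows), error = function(e) {
    pipeline_log("cohort test unavailable: %s", conditionMessage(e))
    list(error = conditionMessage(e))
  })
  jsonlite::write_json(test, file.path(config$out_dir, "cohort_test.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("enrich: %d sample(s), mean relative rate %.3g",
               nrow(rows), mean(rows$relative_rate, na.rm = TRUE))
  list(results = rows, test = test)
}

sv_smoothed_track <- function(svs, assembly, config) {
  moving_average(bin_counts(breakpoints(svs), assembly, config$bin_size),
                 config$span_bins)
}

stage_kataegis <- function(config) {
  co <- load_cohort(config)
  welch <- list()
  out <- list()
  for (s in co$samples) {
    pts <- inter_snv_distances(s$snvs)
    clusters <- call_kataegis(s$snvs, config$kataegis_max_gap,
                              config$kataegis_min_count)
    labels <- classify_bins_by_sv(
      sv_smoothed_track(s$svs, co$assembly, config), config$fold_threshold)
    lab_col <- unlist(lapply(seq_len(nrow(pts)), function(i)
      labels[[pts$chrom[i]]][floor(pts$pos[i] / attr(labels, "bin_size")) + 1L]))
    rain <- cbind(pts, bin_label = if (nrow(pts)) lab_col else character())
    write.table(rain,
                file.path(config$out_dir, paste0(s$sample_id, ".rainfall.tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write_clusters_bed(clusters,
                       file.path(config$out_dir,
                                 paste0(s$sample_id, ".kataegis.bed")))
    welch[[s$sample_id]] <- tryCatch(
      compare_distances_by_region(pts, labels, exclude_kataegis = TRUE,
                                  clusters = clusters),
      error = function(e) list(error = conditionMessage(e)))
    out[[s$sample_id]] <- list(clusters = clusters,
                               welch = welch[[s$sample_id]])
  }
  jsonlite::write_json(welch, file.path(config$out_dir, "kataegis_welch.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("kataegis: %d sample(s) processed", length(out))
  out
}

# pool all samples' variants into cohort-level tracks
pooled_tracks <- function(co, config) {
  all_bp <- do.call(rbind, lapply(co$samples, function(s) breakpoints(s$svs)))
  all_snv <- do.call(rbind, lapply(co$samples, function(s)
    data.frame(chrom = s$snvs$chrom, pos = s$snvs$pos,
               stringsAsFactors = FALSE)))
  list(sv = moving_average(bin_counts(all_bp, co$assembly, config$bin_size),
                           config$span_bins),
       snv = moving_average(bin_counts(all_snv, co$assembly, config$bin_size),
                            config$span_bins))
}

stage_echo <- function(config) {
  co <- load_cohort(config)
  tr <- pooled_tracks(co, config)
  peaks <- find_peaks(tr$sv, config$fold_threshold)
  if (nrow(peaks) == 0L) {
    pipeline_log("echo: no qualifying SV peaks at fold %.3g",
                 config$fold_threshold)
    summary <- list(n_peaks = 0L, score = NA_real_,
                    fold_threshold = config$fold_threshold,
                    flank_bp = config$flank_bp)
  } else {
    prof <- echo_profile(peaks, tr$snv, config$flank_bp)
    write_echo_profile(prof, file.path(config$out_dir, "echo_profile.tsv"))
    summary <- list(n_peaks = prof$n_peaks,
                    score = echo_enrichment_score(prof),
                    fold_threshold = config$fold_threshold,
                    flank_bp = config$flank_bp)
  }
  jsonlite::write_json(summary, file.path(config$out_dir, "echo_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("echo: %d peak(s), score %.3g", summary$n_peaks,
               if (is.na(summary$score)) NA else summary$score)
  summary
}

stage_correlate <- function(config) {
  co <- load_cohort(config)
  n_snv <- vapply(co$samples, function(s) nrow(s$snvs), numeric(1))
  n_sv <- vapply(co$samples, function(s) nrow(s$svs), numeric(1))
  at <- t(vapply(co$samples, function(s) stratify_by_base_pair(s$snvs),
                 numeric(2)))
  out <- list(snv_vs_sv = tryCatch(pearson_correlation(n_sv, n_snv),
                                   error = function(e) list(error = conditionMessage(e))))
  sid <- vapply(co$samples, `[[`, "", "sample_id")
  age <- co$meta$age[match(sid, co$meta$sample_id)]
  if (!all(is.na(age))) {
    clock <- (co$meta$SBS1 + co$meta$SBS5)[match(sid, co$meta$sample_id)]
    out$clock_vs_age <- tryCatch(pearson_correlation(age, clock),
                                 error = function(e) list(error = conditionMessage(e)))
    out$snv_vs_age <- tryCatch(pearson_correlation(age, n_snv),
                               error = function(e) list(error = conditionMessage(e)))
    if (is.null(out$snv_vs_sv$error) && is.null(out$snv_vs_age$error))
      out$fisher_sv_vs_age <- compare_correlations_fisher(
        out$snv_vs_sv$r, out$snv_vs_sv$n, out$snv_vs_age$r, out$snv_vs_age$n)
  }
  out$slope_at <- tryCatch(linear_slope(n_sv, at[, "AT"]),
                           error = function(e) list(error = conditionMessage(e)))
  out$slope_gc <- tryCatch(linear_slope(n_sv, at[, "GC"]),
                           error = function(e) list(error = conditionMessage(e)))
  jsonlite::write_json(out, file.path(config$out_dir, "correlate.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("correlate: %d sample(s)", length(co$samples))
  out
}

stage_tallies <- function(config) {
  if (is.null(config$regions)) stop("tallies stage needs a regions BED path")
  co <- load_cohort(config)
  regions <- read_bed(config$regions)
  if (is.null(regions$name)) regions$name <- sprintf("region_%d",
                                                     seq_len(nrow(regions)))
  per_sample <- lapply(co$samples, function(s)
    region_tallies(regions, s$snvs, s$svs))
  agg <- per_sample[[1]][, c("region_id", "chrom", "start", "end")]
  agg$n_cases_both <- Reduce(`+`, lapply(per_sample, function(t)
    as.integer(t$has_both)))
  agg$total_sv_breakpoints <- Reduce(`+`, lapply(per_sample,
                                                 `[[`, "n_sv_breakpoints"))
  agg$total_snv <- Reduce(`+`, lapply(per_sample, `[[`, "n_snv"))
  write.table(agg, file.path(config$out_dir, "region_tallies.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  pipeline_log("tallies: %d region(s)", nrow(agg))
  agg
}

stage_report <- function(config) {
  files <- c("cohort_test.json", "kataegis_welch.json", "echo_summary.json",
             "correlate.json")
  report <- list()
  for (f in files) {
    p <- file.path(config$out_dir, f)
    if (file.exists(p))
      report[[sub("\\.json$", "", f)]] <-
        jsonlite::read_json(p, simplifyVector = FALSE)
  }
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log("report: merged %d stage result(s)", length(report))
  report
}
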