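# Readers and writers for the plain-text formats the pipeline touches:
# VCF 4.x (SNVs), BEDPE (SVs), BED (masks / regions), chrom-sizes TSV.
# Internal coordinates are 0-based; VCF is 1-based on disk, BED/BEDPE 0-based.

#' Read somatic SNVs from a VCF file
#'
#' Only rows whose REF and every ALT allele are single bases in A,C,G,T are
#' kept; multi-allelic rows are split into one record per ALT; everything else
#' (indels, MNVs, symbolic alleles) is skipped and counted. VCF 1-based POS is
#' converted to the internal 0-based convention.
#'
#' @param path Path to a VCF 4.x text file.
#' @param assembly A [genome_assembly()].
#' @param strip_chr_prefix If TRUE, a leading "chr" is removed from VCF
#'   chromosome names before matching the assembly.
#' @param on_missing_chrom "skip" (default) drops rows on chromosomes absent
#'   from the assembly (counted in `n_skipped`); "fail" raises an error.
#' @return An [snv_set()]; attribute `n_skipped` counts dropped rows.
#' @export
read_snvs <- function(path, assembly, strip_chr_prefix = FALSE,
                      on_missing_chrom = c("skip", "fail")) {
  on_missing_chrom <- match.arg(on_missing_chrom)
  stopifnot(inherits(assembly, "genome_assembly"))
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  n_skipped <- 0L
  if (is.null(fix) || nrow(fix) == 0L) {
    out <- snv_set(assembly = assembly)
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  chrom <- as.character(fix[, "CHROM"])
  if (strip_chr_prefix) chrom <- sub("^chr", "", chrom)
  pos1 <- as.numeric(fix[, "POS"])
  ref <- toupper(as.character(fix[, "REF"]))
  alt <- toupper(as.character(fix[, "ALT"]))

  alt_split <- strsplit(alt, ",", fixed = TRUE)
  n_alt <- lengths(alt_split)
  chrom <- rep(chrom, n_alt); pos1 <- rep(pos1, n_alt); ref <- rep(ref, n_alt)
  alt <- unlist(alt_split, use.names = FALSE)

  is_snv <- ref %in% BASES & alt %in% BASES & ref != alt
  n_skipped <- n_skipped + sum(!is_snv)
  chrom <- chrom[is_snv]; pos1 <- pos1[is_snv]; ref <- ref[is_snv]; alt <- alt[is_snv]

  known <- chrom %in% assembly$chrom
  if (!all(known)) {
    if (on_missing_chrom == "fail")
      stop("VCF chromosome(s) absent from assembly: ",
           paste(unique(chrom[!known]), collapse = ", "))
    n_skipped <- n_skipped + sum(!known)
    chrom <- chrom[known]; pos1 <- pos1[known]; ref <- ref[known]; alt <- alt[known]
  }
  pos0 <- pos1 - 1
  L <- if (length(chrom)) chrom_length(assembly, chrom) else numeric()
  if (any(pos0 < 0 | pos0 >= L))
    stop("VCF POS outside chromosome bounds")
  out <- snv_set(chrom, pos0, ref, alt, assembly)
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write SNVs as a minimal VCF 4.2 file
#'
#' Emits header plus CHROM/POS/ID/REF/ALT/QUAL/FILTER/INFO columns with
#' positions converted back to 1-based, suitable for external signature tools.
#' Reading the result back with [read_snvs()] reproduces the input set.
#'
#' @param snvs An [snv_set()].
#' @param path Output path.
#' @export
write_snv_subset <- function(snvs, path) {
  stopifnot(inherits(snvs, "snv_set"))
  assembly <- assembly_of(snvs)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##source=svecho",
    sprintf("##contig=<ID=%s,length=%.0f>", assembly$chrom,
            unname(assembly$length)),
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")), con)
  if (nrow(snvs) > 0L) {
    writeLines(sprintf("%s\t%.0f\t.\t%s\t%s\t.\t.\t.",
                       snvs$chrom, snvs$pos + 1, snvs$ref, snvs$alt), con)
  }
  invisible(path)
}

#' Read somatic SVs from a BEDPE file
#'
#' Expects at least six columns (chrom1, start1, end1, chrom2, start2, end2);
#' the breakpoint of each mate is the interval start (BEDPE is 0-based
#' half-open). The SV class is parsed case-insensitively from `class_col`
#' when present, else set to "unknown".
#'
#' @param path Path to a BEDPE text file ("#"-prefixed header lines ignored).
#' @param assembly A [genome_assembly()].
#' @param class_col Column index holding the SV class (default 7).
#' @param strip_chr_prefix As in [read_snvs()].
#' @return An [sv_set()].
#' @export
read_svs <- function(path, assembly, class_col = 7L, strip_chr_prefix = FALSE) {
  stopifnot(inherits(assembly, "genome_assembly"))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(sv_set(assembly = assembly))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 6L))
    stop("BEDPE rows must have at least 6 tab-separated columns")
  field <- function(i) vapply(parts, `[[`, "", i)
  chrom1 <- field(1L); chrom2 <- field(4L)
  if (strip_chr_prefix) {
    chrom1 <- sub("^chr", "", chrom1); chrom2 <- sub("^chr", "", chrom2)
  }
  pos1 <- suppressWarnings(as.numeric(field(2L)))
  pos2 <- suppressWarnings(as.numeric(field(5L)))
  if (anyNA(pos1) || anyNA(pos2)) stop("non-numeric BEDPE start coordinate")
  cls <- if (all(lengths(parts) >= class_col))
    field(class_col) else rep("unknown", length(parts))
  sv_set(chrom1, pos1, chrom2, pos2, cls, assembly)
}

#' Read a BED file of intervals (masks or named regions)
#'
#' @param path BED path; 0-based half-open intervals; optional 4th name column.
#' @return Data frame with columns chrom, start, end and, when present, name.
#' @export
read_bed <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#") &
                   !startsWith(lines, "track")]
  if (length(lines) == 0L)
    return(data.frame(chrom = character(), start = numeric(), end = numeric(),
                      stringsAsFactors = FALSE))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3L)) stop("BED rows need chrom, start, end")
  out <- data.frame(
    chrom = vapply(parts, `[[`, "", 1L),
    start = as.numeric(vapply(parts, `[[`, "", 2L)),
    end = as.numeric(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE)
  if (all(lengths(parts) >= 4L)) out$name <- vapply(parts, `[[`, "", 4L)
  if (any(is.na(out$start) | is.na(out$end)) || any(out$end <= out$start))
    stop("invalid BED interval (need numeric start < end)")
  out
}

#' Write SVs as a BEDPE file
#'
#' Each breakpoint becomes a 1 bp interval (0-based half-open); column 7
#' carries the SV class. [read_svs()] on the result reproduces the set.
#'
#' @param svs An [sv_set()].
#' @param path Output path.
#' @export
write_svs_bedpe <- function(svs, path) {
  stopifnot(inherits(svs, "sv_set"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(svs) > 0L)
    writeLines(sprintf("%s\t%.0f\t%.0f\t%s\t%.0f\t%.0f\t%s",
                       svs$chrom1, svs$pos1, svs$pos1 + 1,
                       svs$chrom2, svs$pos2, svs$pos2 + 1,
                       toupper(substr(svs$sv_class, 1, 3))), con)
  invisible(path)
}

#' Write kataegis clusters as BED
#'
#' @param clusters Output of [call_kataegis()].
#' @param path Output path.
#' @export
write_clusters_bed <- function(clusters, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (nrow(clusters) > 0L)
    writeLines(sprintf("%s\t%.0f\t%.0f\tkataegis_n%d",
                       clusters$chrom, clusters$start_pos,
                       clusters$end_pos + 1, clusters$n_snvs), con)
  invisible(path)
}
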