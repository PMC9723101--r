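BASES <- c("A", "C", "G", "T")

#' Construct a set of somatic SNVs
#'
#' Positions are 0-based internally (VCF input is converted on read). Records
#' are sorted by assembly chromosome order and position; duplicate positions
#' are allowed (they are flagged downstream by the rainfall machinery).
#'
#' @param chrom Character chromosome names.
#' @param pos Numeric 0-based positions.
#' @param ref,alt Single reference / alternate bases in `A,C,G,T`; `ref != alt`
#'   row-wise.
#' @param assembly A [genome_assembly()]; positions are validated against it.
#' @return A data frame of class `snv_set` with columns chrom, pos, ref, alt
#'   and the assembly stored as an attribute.
#' @export
snv_set <- function(chrom = character(), pos = numeric(),
                    ref = character(), alt = character(), assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  n <- length(pos)
  if (length(chrom) != n || length(ref) != n || length(alt) != n)
    stop("chrom, pos, ref, alt must have equal length")
  chrom <- as.character(chrom); ref <- toupper(ref); alt <- toupper(alt)
  pos <- as.numeric(pos)
  if (n > 0L) {
    if (!all(ref %in% BASES) || !all(alt %in% BASES))
      stop("ref and alt must be single bases in A,C,G,T")
    if (any(ref == alt)) stop("ref must differ from alt")
    L <- chrom_length(assembly, chrom)
    if (any(pos < 0 | pos >= L))
      stop("SNV position outside its chromosome")
  }
  df <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                   stringsAsFactors = FALSE)
  ord <- order(chrom_factor(df$chrom, assembly), df$pos)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, assembly = assembly, class = c("snv_set", "data.frame"))
}

#' Construct a set of somatic SVs
#'
#' Each SV is a pair of breakpoints with a class. Translocation class with
#' both breakpoints on one chromosome (or a non-translocation spanning two
#' chromosomes) triggers a warning, not an error.
#'
#' @param chrom1,pos1,chrom2,pos2 Breakpoint coordinates, 0-based.
#' @param sv_class Character; one of duplication, inversion, deletion,
#'   translocation, unknown (case-insensitive; common abbreviations DEL, DUP,
#'   INV, TRA, BND are recognized).
#' @param assembly A [genome_assembly()].
#' @return A data frame of class `sv_set`.
#' @export
sv_set <- function(chrom1 = character(), pos1 = numeric(),
                   chrom2 = character(), pos2 = numeric(),
                   sv_class = character(), assembly) {
  stopifnot(inherits(assembly, "genome_assembly"))
  n <- length(pos1)
  if (length(chrom1) != n || length(chrom2) != n || length(pos2) != n)
    stop("breakpoint columns must have equal length")
  if (length(sv_class) == 0L && n > 0L) sv_class <- rep("unknown", n)
  if (length(sv_class) != n) stop("sv_class length mismatch")
  sv_class <- normalize_sv_class(sv_class)
  chrom1 <- as.character(chrom1); chrom2 <- as.character(chrom2)
  pos1 <- as.numeric(pos1); pos2 <- as.numeric(pos2)
  if (n > 0L) {
    L1 <- chrom_length(assembly, chrom1); L2 <- chrom_length(assembly, chrom2)
    if (any(pos1 < 0 | pos1 >= L1) || any(pos2 < 0 | pos2 >= L2))
      stop("SV breakpoint outside its chromosome")
    inter <- chrom1 != chrom2
    bad_tra <- sv_class == "translocation" & !inter
    bad_intra <- sv_class %in% c("duplication", "inversion", "deletion") & inter
    if (any(bad_tra))
      warning(sum(bad_tra), " translocation(s) with both breakpoints on one chromosome")
    if (any(bad_intra))
      warning(sum(bad_intra), " intra-chromosomal class(es) spanning two chromosomes")
  }
  df <- data.frame(chrom1 = chrom1, pos1 = pos1, chrom2 = chrom2, pos2 = pos2,
                   sv_class = sv_class, stringsAsFactors = FALSE)
  ord <- order(chrom_factor(df$chrom1, assembly), df$pos1)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  structure(df, assembly = assembly, class = c("sv_set", "data.frame"))
}

SV_CLASSES <- c("duplication", "inversion", "deletion", "translocation", "unknown")

normalize_sv_class <- function(x) {
  x <- tolower(as.character(x))
  map <- c(dup = "duplication", duplication = "duplication",
           inv = "inversion", inversion = "inversion",
           del = "deletion", deletion = "deletion",
           tra = "translocation", trans = "translocation", bnd = "translocation",
           translocation = "translocation", unk = "unknown",
           unknown = "unknown")
  out <- unname(map[x])
  out[is.na(out)] <- "unknown"
  out
}

#' Breakpoints of an SV set
#'
#' Flattens an SV set into one row per breakpoint (two per SV), carrying the
#' originating SV row index.
#'
#' @param svs An [sv_set()].
#' @return Data frame with columns chrom, pos, sv_index.
#' @export
breakpoints <- function(svs) {
  stopifnot(inherits(svs, "sv_set"))
  data.frame(
    chrom = c(svs$chrom1, svs$chrom2),
    pos = c(svs$pos1, svs$pos2),
    sv_index = rep(seq_len(nrow(svs)), 2L),
    stringsAsFactors = FALSE
  )
}

assembly_of <- function(x) {
  a <- attr(x, "assembly")
  if (is.null(a)) stop("object carries no genome assembly")
  a
}

# positions split per chromosome, in assembly order
positions_by_chrom <- function(chrom, pos, assembly) {
  out <- split(pos, chrom_factor(chrom, assembly))
  lapply(out, sort)
}
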