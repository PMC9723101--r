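#' Construct a genome assembly
#'
#' An assembly is the ordered set of chromosome names and lengths used by every
#' downstream operation: it fixes the chromosome sort order, bounds coordinate
#' validation, and supplies the total genome length that the random-expectation
#' enrichment formula divides by.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Numeric vector of positive chromosome lengths in base pairs.
#' @return An object of class `genome_assembly`: a list with elements
#'   `chrom`, `length` (named numeric) and `total_length`.
#' @examples
#' genome_assembly(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_assembly <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (length(chrom) == 0L) stop("assembly must contain at least one chromosome")
  if (length(chrom) != length(length)) stop("chrom and length differ in length")
  if (anyDuplicated(chrom)) stop("duplicate chromosome names: ",
                                 paste(unique(chrom[duplicated(chrom)]), collapse = ", "))
  if (any(!is.finite(length)) || any(length < 1) || any(length != floor(length)))
    stop("chromosome lengths must be positive integers")
  structure(
    list(chrom = chrom,
         length = setNames(length, chrom),
         total_length = sum(length)),
    class = "genome_assembly"
  )
}

#' Read a two-column chromosome-sizes file
#'
#' @param path Path to a TSV with columns name and length (no header).
#' @return A [genome_assembly()] in file order.
#' @export
read_chrom_sizes <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty chrom-sizes file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2L)) stop("chrom-sizes rows must have two tab-separated columns")
  nm <- vapply(parts, `[[`, "", 1L)
  len_chr <- vapply(parts, `[[`, "", 2L)
  len <- suppressWarnings(as.numeric(len_chr))
  if (any(is.na(len))) stop("non-numeric chromosome length: ",
                            paste(len_chr[is.na(len)], collapse = ", "))
  genome_assembly(nm, len)
}

#' @export
print.genome_assembly <- function(x, ...) {
  cat(sprintf("<genome_assembly> %d chromosome(s), total %.0f bp\n",
              length(x$chrom), x$total_length))
  invisible(x)
}

chrom_length <- function(assembly, chrom) {
  L <- assembly$length[chrom]
  if (anyNA(L)) stop("chromosome(s) absent from assembly: ",
                     paste(unique(chrom[is.na(L)]), collapse = ", "))
  unname(L)
}

# genome-order factor used to sort variant tables
chrom_factor <- function(chrom, assembly) factor(chrom, levels = assembly$chrom)
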