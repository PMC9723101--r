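# Fixture builders and independent brute-force / closed-form oracles used
# across the suite. Oracles are deliberately naive implementations, kept
# separate from the package's code paths.

tiny_assembly <- function(...) {
  len <- c(...)
  if (length(len) == 0L) len <- c(chr1 = 1e6, chr2 = 5e5)
  genome_assembly(names(len), unname(len))
}

# SNV set with cycling ref/alt bases unless given
make_snvs <- function(chrom, pos, assembly, ref = NULL, alt = NULL) {
  n <- length(pos)
  if (is.null(ref)) ref <- rep(c("A", "C", "G", "T"), length.out = n)
  if (is.null(alt)) alt <- rep(c("G", "T", "A", "C"), length.out = n)
  snv_set(rep(chrom, length.out = n), pos, ref, alt, assembly)
}

make_svs <- function(chrom, pos, assembly, chrom2 = NULL, pos2 = NULL,
                     cls = "deletion") {
  n <- length(pos)
  if (is.null(chrom2)) chrom2 <- chrom
  if (is.null(pos2)) pos2 <- pos + 1
  sv_set(rep(chrom, length.out = n), pos,
         rep(chrom2, length.out = n), pos2,
         rep(cls, length.out = n), assembly)
}

# brute-force double loop: distinct SNVs within range of >= 1 breakpoint
oracle_observed <- function(snv_chrom, snv_pos, bp_chrom, bp_pos, range_bp) {
  count <- 0L
  for (i in seq_along(snv_pos)) {
    hit <- FALSE
    for (j in seq_along(bp_pos)) {
      if (snv_chrom[i] == bp_chrom[j] &&
          abs(snv_pos[i] - bp_pos[j]) <= range_bp) {
        hit <- TRUE
        break
      }
    }
    if (hit) count <- count + 1L
  }
  count
}

# exhaustive kataegis oracle on one chromosome: every contiguous subsequence
# is tested against the gap rule; maximal qualifying ones are reported
oracle_kataegis_chrom <- function(p, max_gap, min_count) {
  p <- sort(p)
  n <- length(p)
  ok <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in i:n) {
      gaps_ok <- TRUE
      if (j > i) {
        for (k in (i + 1):j) {
          if (p[k] - p[k - 1] > max_gap) { gaps_ok <- FALSE; break }
        }
      }
      ok[i, j] <- gaps_ok && (j - i + 1 >= min_count)
    }
  }
  out <- NULL
  for (i in seq_len(n)) {
    for (j in i:n) {
      if (!ok[i, j]) next
      maximal <- (i == 1 || !ok[i - 1, j]) && (j == n || !ok[i, j + 1])
      # extendability in either direction voids maximality
      if (i > 1 && p[i] - p[i - 1] <= max_gap) maximal <- FALSE
      if (j < n && p[j + 1] - p[j] <= max_gap) maximal <- FALSE
      if (maximal)
        out <- rbind(out, data.frame(start_pos = p[i], end_pos = p[j],
                                     n_snvs = j - i + 1))
    }
  }
  out
}

# independent neighbor-scan peak oracle with plateau-midpoint policy
oracle_peaks <- function(v) {
  n <- length(v)
  if (n < 2L) return(integer())
  out <- integer()
  i <- 1L
  while (i <= n) {
    j <- i
    while (j < n && v[j + 1L] == v[i]) j <- j + 1L
    left_ok <- (i == 1L) || (v[i - 1L] < v[i])
    right_ok <- (j == n) || (v[j + 1L] < v[i])
    if (left_ok && right_ok && !(i == 1L && j == n))
      out <- c(out, i + floor((j - i) / 2))
    i <- j + 1L
  }
  out
}

# textbook formula oracles, independent of stats::t.test / cor.test
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(statistic = t, df = df, p = 2 * stats::pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - mean(x); sy <- y - mean(y)
  r <- sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
  t <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, t = t, p = 2 * stats::pt(-abs(t), n - 2))
}

oracle_fisher_z <- function(r1, n1, r2, n2) {
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

oracle_slope <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  list(slope = b, intercept = mean(y) - b * mean(x))
}

# small random variant instance on a tiny assembly
random_instance <- function(assembly, n_snv, n_bp) {
  chs <- assembly$chrom
  sc <- sample(chs, n_snv, replace = TRUE)
  sp <- floor(runif(n_snv) * unname(assembly$length[sc]))
  bc <- sample(chs, n_bp, replace = TRUE)
  bp <- floor(runif(n_bp) * unname(assembly$length[bc]))
  list(snv_chrom = sc, snv_pos = sp, bp_chrom = bc, bp_pos = bp)
}

# strip class and bookkeeping attributes for value-only comparisons
plain_df <- function(x) {
  df <- as.data.frame(x)
  attributes(df) <- attributes(df)[c("names", "row.names")]
  class(df) <- "data.frame"
  df
}
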