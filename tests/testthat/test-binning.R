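test_that("bin_counts assigns by floor division and conserves totals", {
  a <- tiny_assembly(c1 = 2e6)
  tr <- bin_counts(list(c1 = c(0, 999999, 1000000)), a, 1e6)
  expect_equal(tr$values$c1, c(2, 1))

  expect_equal(bin_counts(list(c1 = numeric()), a, 1e6)$values$c1, c(0, 0))
  # bin larger than the chromosome -> single bin holding everything
  big <- bin_counts(list(c1 = c(5, 10, 1999999)), a, 1e7)
  expect_equal(big$values$c1, 3)

  expect_error(bin_counts(list(c1 = 2e6), a, 1e6), "outside")
  expect_error(bin_counts(list(c1 = 1), a, 0), "bin_size")
})

test_that("binning conserves counts and is consistent across bin sizes", {
  a <- tiny_assembly(c1 = 3.7e6, c2 = 1.2e6)
  set.seed(11)
  pos <- list(c1 = floor(runif(500) * 3.7e6), c2 = floor(runif(200) * 1.2e6))
  t100k <- bin_counts(pos, a, 1e5)
  t1m <- bin_counts(pos, a, 1e6)
  expect_equal(sum(unlist(t100k$values)), 700)
  expect_equal(sum(t1m$values$c1), 500)
  # summing 10 consecutive 100 kb bins reproduces the 1 Mb binning
  for (ch in c("c1", "c2")) {
    v <- t100k$values[[ch]]
    grp <- floor((seq_along(v) - 1) / 10)
    expect_equal(as.numeric(tapply(v, grp, sum)), t1m$values[[ch]],
                 ignore_attr = TRUE)
  }
})

test_that("moving_average uses truncated centered windows", {
  a <- tiny_assembly(c1 = 5e6)
  tr <- binned_track(a, 1e6, list(c1 = c(0, 0, 10, 0, 0)))
  sm <- moving_average(tr, 5)
  expect_equal(sm$values$c1[3], 2)
  expect_equal(sm$values$c1[1], 10 / 3)
  expect_equal(sm$values$c1[5], 10 / 3)

  const <- binned_track(a, 1e6, list(c1 = rep(7, 5)))
  expect_equal(moving_average(const, 3)$values$c1, rep(7, 5))
  expect_equal(moving_average(tr, 1)$values$c1, tr$values$c1)
  expect_error(moving_average(tr, 4), "odd")
})

test_that("moving_average preserves the mean over full interior windows", {
  a <- tiny_assembly(c1 = 2e7)
  set.seed(3)
  v <- rpois(20, 5)
  sm <- moving_average(binned_track(a, 1e6, list(c1 = as.numeric(v))), 5)
  # interior bin i's window mean sums each input bin once when averaged
  interior <- 3:18
  expect_equal(mean(sm$values$c1[interior]),
               mean(vapply(interior, function(i) mean(v[(i - 2):(i + 2)]),
                           numeric(1))))
})

test_that("genomic_average includes zero bins and honors masks", {
  a <- tiny_assembly(c1 = 3e6)
  ones <- binned_track(a, 1e6, list(c1 = rep(1, 3)))
  expect_equal(genomic_average(ones), 1)
  tr <- binned_track(a, 1e6, list(c1 = c(0, 0, 6)))
  expect_equal(genomic_average(tr), 2)
  mask <- data.frame(chrom = "c1", start = 2e6, end = 3e6)
  expect_equal(genomic_average(tr, mask), 0)
  allmask <- data.frame(chrom = "c1", start = 0, end = 3e6)
  expect_error(genomic_average(tr, allmask), "masked")
})

test_that("find_peaks returns thresholded strict local maxima with plateau midpoints", {
  a <- tiny_assembly(c1 = 5e6)
  tr <- binned_track(a, 1e6, list(c1 = c(1, 1, 5, 1, 1)))
  pk <- find_peaks(tr, 2)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$bin_index, 2L)
  expect_equal(pk$fold_over_mean, 5 / 1.8)
  expect_equal(pk$center_pos, 2.5e6)

  flat <- binned_track(a, 1e6, list(c1 = rep(3, 5)))
  expect_equal(nrow(find_peaks(flat, 1)), 0L)

  a4 <- tiny_assembly(c1 = 4e6)
  plateau <- binned_track(a4, 1e6, list(c1 = c(0, 4, 4, 0)))
  pk2 <- find_peaks(plateau, 1)
  expect_equal(pk2$bin_index, 1L)

  expect_error(find_peaks(tr, 0.5), "fold_threshold")
})

test_that("find_peaks agrees with an exhaustive neighbor-scan oracle", {
  set.seed(99)
  for (rep in 1:200) {
    n <- sample(2:60, 1)
    v <- sample(0:5, n, replace = TRUE)
    a <- tiny_assembly(c1 = n * 1e6)
    pk <- find_peaks(binned_track(a, 1e6, list(c1 = as.numeric(v))), 1)
    g <- mean(v)
    want <- oracle_peaks(v)
    want <- want[v[want] >= g]
    expect_equal(pk$bin_index, as.integer(want - 1L))
  }
})

test_that("high_loci intersects per-track fold thresholds", {
  a <- tiny_assembly(c1 = 3e6)
  sv <- binned_track(a, 1e6, list(c1 = c(0, 10, 0)))
  snv <- binned_track(a, 1e6, list(c1 = c(0, 8, 0)))
  hl <- high_loci(sv, snv, 2)
  expect_equal(hl$bin_index, 1L)

  flat <- binned_track(a, 1e6, list(c1 = rep(2, 3)))
  expect_equal(nrow(high_loci(sv, flat, 2)), 0L)
  expect_equal(nrow(high_loci(flat, flat, 1)), 3L)

  b <- tiny_assembly(c1 = 4e6)
  other <- binned_track(b, 1e6, list(c1 = rep(1, 4)))
  expect_error(high_loci(sv, other), "share")
})

test_that("track TSV export writes clipped half-open bins", {
  a <- tiny_assembly(c1 = 2.5e6)
  tr <- bin_counts(list(c1 = c(0, 2.4e6)), a, 1e6)
  tf <- withr::local_tempfile()
  write_track(tr, tf)
  df <- read.table(tf, header = TRUE, sep = "\t")
  expect_equal(df$bin_end, c(1e6, 2e6, 2.5e6))
  expect_equal(df$value, c(1, 0, 1))
})

test_that("rotate_track permutes bins circularly and preserves multisets", {
  a <- tiny_assembly(c1 = 5e6, c2 = 3e6)
  tr <- binned_track(a, 1e6, list(c1 = c(1, 2, 3, 4, 5), c2 = c(9, 8, 7)))
  rot <- rotate_track(tr, offsets = c(2, 1))
  expect_equal(rot$values$c1, c(4, 5, 1, 2, 3))
  expect_equal(rot$values$c2, c(7, 9, 8))
  set.seed(1)
  r2 <- rotate_track(tr)
  expect_equal(sort(r2$values$c1), 1:5, ignore_attr = TRUE)
})
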