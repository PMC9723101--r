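test_that("inter_snv_distances computes per-chromosome gaps and zones", {
  a <- tiny_assembly(chr1 = 1e7, chr2 = 1e7)
  s <- make_snvs("chr1", c(100, 300, 1300), a)
  pts <- inter_snv_distances(s)
  expect_equal(pts$dist_to_prev, c(NA, 200, 1000))
  expect_equal(pts$zone, c(NA, "lt_1kb", "kb_1_to_Mb_1"))

  one <- inter_snv_distances(make_snvs("chr1", 5, a))
  expect_equal(nrow(one), 1L)
  expect_true(is.na(one$dist_to_prev))

  # no cross-chromosome distances
  two <- snv_set(c("chr1", "chr2"), c(100, 150), c("A", "A"), c("C", "C"), a)
  pts2 <- inter_snv_distances(two)
  expect_true(all(is.na(pts2$dist_to_prev)))

  # >= 1 Mb zone and duplicate-position ties
  far <- snv_set(rep("chr1", 3), c(0, 0, 2e6), rep("A", 3), rep("C", 3), a)
  pts3 <- inter_snv_distances(far)
  expect_equal(pts3$zone[2:3], c("lt_1kb", "ge_1Mb"))
  expect_true(pts3$is_tie[2])
})

test_that("call_kataegis applies the chain rule with maximal runs", {
  a <- tiny_assembly(chr1 = 1e7)
  c1 <- call_kataegis(make_snvs("chr1", c(100, 600, 1050), a))
  expect_equal(nrow(c1), 1L)
  expect_equal(c(c1$start_pos, c1$end_pos, c1$n_snvs), c(100, 1050, 3))

  expect_equal(nrow(call_kataegis(make_snvs("chr1", c(100, 1200, 2300), a))), 0L)

  c3 <- call_kataegis(make_snvs("chr1", c(0, 500, 1000, 5000, 5500, 6000), a))
  expect_equal(nrow(c3), 2L)
  expect_equal(c3$n_snvs, c(3L, 3L))
  expect_equal(c3$start_pos, c(0, 5000))

  expect_error(call_kataegis(make_snvs("chr1", 1:5 * 100, a), max_gap = 0),
               "max_gap")
  expect_error(call_kataegis(make_snvs("chr1", 1:5 * 100, a), min_count = 1),
               "min_count")
})

test_that("call_kataegis equals the exhaustive oracle on random instances", {
  a <- tiny_assembly(chr1 = 1e5)
  set.seed(21)
  for (rep in 1:60) {
    n <- sample(3:40, 1)
    p <- sort(sample(0:2e4, n))
    got <- call_kataegis(snv_set(rep("chr1", n), p, rep("A", n),
                                 rep("C", n), a))
    want <- oracle_kataegis_chrom(p, 1000, 3)
    if (is.null(want)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(got$start_pos, want$start_pos)
      expect_equal(got$end_pos, want$end_pos)
      expect_equal(got$n_snvs, want$n_snvs)
    }
  }
})

test_that("called clusters are internally dense and pairwise unmergeable", {
  a <- tiny_assembly(chr1 = 1e6)
  set.seed(31)
  p <- sort(sample(0:4e4, 120))
  s <- snv_set(rep("chr1", 120), p, rep("A", 120), rep("C", 120), a)
  cl <- call_kataegis(s)
  for (k in seq_len(nrow(cl))) {
    member <- p[p >= cl$start_pos[k] & p <= cl$end_pos[k]]
    expect_true(all(diff(member) <= 1000))
    expect_gte(length(member), 3L)
  }
  if (nrow(cl) > 1L)
    expect_true(all(cl$start_pos[-1] - cl$end_pos[-nrow(cl)] > 1000))
})

test_that("the strict-window alternative requires min_count within one window", {
  a <- tiny_assembly(chr1 = 1e7)
  # chain qualifies (gaps 600+600) but no 1 kb window holds 3 SNVs
  s <- make_snvs("chr1", c(0, 600, 1200), a)
  expect_equal(nrow(call_kataegis(s, method = "chain")), 1L)
  expect_equal(nrow(call_kataegis(s, method = "window")), 0L)
  s2 <- make_snvs("chr1", c(0, 400, 800), a)
  w2 <- call_kataegis(s2, method = "window")
  expect_equal(w2$n_snvs, 3L)
})

test_that("classify_bins_by_sv thresholds against the genomic average", {
  a <- tiny_assembly(c1 = 3e6)
  flat <- binned_track(a, 1e6, list(c1 = rep(2, 3)))
  expect_equal(unname(unlist(classify_bins_by_sv(flat, 2))), rep("sv_low", 3))
  expect_equal(unname(unlist(classify_bins_by_sv(flat, 1))), rep("sv_high", 3))
  tr <- binned_track(a, 1e6, list(c1 = c(0, 10, 0)))
  expect_equal(unname(unlist(classify_bins_by_sv(tr, 2))),
               c("sv_low", "sv_high", "sv_low"))
})

test_that("compare_distances_by_region runs Welch on log10 distances by bin label", {
  a <- tiny_assembly(c1 = 4e6)
  # bins 1-2 sv_high (dense SNVs), bins 3-4 sv_low (sparse SNVs)
  sv <- binned_track(a, 1e6, list(c1 = c(10, 10, 0, 0)))
  labels <- classify_bins_by_sv(sv, 2)
  # dense but non-kataegis spacing in sv_high, plus one planted burst
  pos_high <- c(seq(0, 1.9e6, by = 2000),
                c(1000500, 1000700, 1000900, 1001100, 1001300))
  pos_low <- seq(2e6, 3.9e6, by = 20000)
  n <- length(pos_high) + length(pos_low)
  s <- snv_set(rep("c1", n), c(pos_high, pos_low), rep("A", n), rep("C", n), a)
  pts <- inter_snv_distances(s)
  res <- compare_distances_by_region(pts, labels)
  hi <- log10(pts$dist_to_prev[!is.na(pts$dist_to_prev) & pts$pos < 2e6])
  lo <- log10(pts$dist_to_prev[!is.na(pts$dist_to_prev) & pts$pos >= 2e6])
  want <- oracle_welch(hi, lo)
  expect_equal(res$statistic, want$statistic, tolerance = 1e-9)
  expect_equal(res$p_two_sided, want$p, tolerance = 1e-9)
  expect_lt(res$mean_high, res$mean_low)

  # kataegis exclusion drops points inside called clusters
  cl <- call_kataegis(s)
  res2 <- compare_distances_by_region(pts, labels, exclude_kataegis = TRUE,
                                      clusters = cl)
  expect_lt(res2$n_high + res2$n_low, res$n_high + res$n_low)
  expect_error(compare_distances_by_region(pts, labels,
                                           exclude_kataegis = TRUE),
               "clusters")

  # a region class with < 2 distances is an error
  sparse <- make_snvs("c1", c(100, 200, 300), a)
  expect_error(compare_distances_by_region(inter_snv_distances(sparse), labels),
               ">= 2")
})

test_that("identical distance multisets in both groups give t = 0, p = 1", {
  a <- tiny_assembly(c1 = 2e6, c2 = 2e6)
  sv <- binned_track(a, 1e6, list(c1 = c(10, 10), c2 = c(0, 0)))
  labels <- classify_bins_by_sv(sv, 2)
  pos <- c(0, 100, 300, 600)
  s <- snv_set(rep(c("c1", "c2"), each = 4), c(pos, pos),
               rep("A", 8), rep("C", 8), a)
  res <- compare_distances_by_region(inter_snv_distances(s), labels)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_two_sided, 1)
})

test_that("stratify_by_base_pair tallies reference A:T vs G:C", {
  a <- tiny_assembly(chr1 = 1e6)
  s <- snv_set(rep("chr1", 5), 1:5 * 100, c("A", "T", "G", "C", "A"),
               c("C", "C", "A", "A", "C"), a)
  expect_equal(stratify_by_base_pair(s), c(AT = 3L, GC = 2L))
  expect_equal(stratify_by_base_pair(snv_set(assembly = a)),
               c(AT = 0L, GC = 0L))
  g <- snv_set(rep("chr1", 4), 1:4 * 10, rep("G", 4), rep("A", 4), a)
  expect_equal(stratify_by_base_pair(g), c(AT = 0L, GC = 4L))
})
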