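test_that("expected_snv_count evaluates the random-expectation formula exactly", {
  expect_equal(expected_snv_count(3000, 3e9, 100, 1e6), 200, tolerance = 1e-12)
  expect_equal(expected_snv_count(5000, 3e9, 0, 1e6), 0)
  expect_equal(expected_snv_count(1000, 1e8, 5, 1e4), 1, tolerance = 1e-12)
  expect_error(expected_snv_count(10, 0, 5, 1e4), "positive")
  expect_error(expected_snv_count(-1, 1e6, 5, 1e4), "non-negative")
})

test_that("expected_snv_count is linear in each argument", {
  set.seed(5)
  for (rep in 1:50) {
    n_snv <- runif(1, 0, 1e5); G <- runif(1, 1e6, 3e9)
    n_sv <- runif(1, 0, 500); r <- runif(1, 0, 1e7)
    base <- expected_snv_count(n_snv, G, n_sv, r)
    expect_equal(base, n_snv / G * n_sv * 2 * r)
    expect_equal(expected_snv_count(3 * n_snv, G, n_sv, r), 3 * base)
    expect_equal(expected_snv_count(n_snv, G, 5 * n_sv, r), 5 * base)
    expect_equal(expected_snv_count(n_snv, G, n_sv, 2 * r), 2 * base)
  }
})

test_that("observed_snv_near_sv counts distinct SNVs near any breakpoint", {
  a <- tiny_assembly(chr1 = 5e6, chr2 = 5e6)
  snvs <- make_snvs("chr1", c(10, 500000, 2000000), a)
  svs <- make_svs("chr1", 100000, a, pos2 = 100001)
  expect_equal(observed_snv_near_sv(snvs, svs, 1e6), 2L)

  other <- make_snvs("chr2", 1000, a)
  expect_equal(observed_snv_near_sv(other, svs, 1e6), 0L)

  # dedup across overlapping windows
  svs2 <- make_svs("chr1", 100000, a, pos2 = 150000)
  one <- make_snvs("chr1", 120000, a)
  expect_equal(observed_snv_near_sv(one, svs2, 1e6), 1L)
  expect_error(observed_snv_near_sv(snvs, svs, -1), "range_bp")
})

test_that("observed_snv_near_sv boundary is inclusive and count is monotone in range", {
  a <- tiny_assembly(chr1 = 5e6)
  snvs <- make_snvs("chr1", c(0, 1000, 2001), a)
  svs <- make_svs("chr1", 2000, a, pos2 = 2000 + 1)
  expect_equal(observed_snv_near_sv(snvs, svs, 1000), 2L)  # 1000 away inclusive
  expect_equal(observed_snv_near_sv(snvs, svs, 999), 1L)
  counts <- vapply(c(0, 10, 1000, 1e4, 5e6), function(r)
    observed_snv_near_sv(snvs, svs, r), numeric(1))
  expect_true(all(diff(counts) >= 0))
  expect_equal(counts[length(counts)], 3)  # saturates at all SNVs on the chromosome
})

test_that("observed_snv_near_sv matches the brute-force double loop", {
  a <- tiny_assembly(c1 = 2e6, c2 = 1e6, c3 = 5e5)
  set.seed(77)
  for (rep in 1:40) {
    inst <- random_instance(a, sample(0:300, 1), sample(0:20, 1))
    n <- length(inst$snv_pos)
    snvs <- make_snvs("c1", numeric(), a)
    if (n > 0)
      snvs <- snv_set(inst$snv_chrom, inst$snv_pos,
                      rep("A", n), rep("C", n), a)
    m <- length(inst$bp_pos)
    svs <- if (m == 0) sv_set(assembly = a) else
      sv_set(inst$bp_chrom, inst$bp_pos,
             inst$bp_chrom, inst$bp_pos, rep("unknown", m), a)
    r <- sample(c(0, 100, 1e4, 2e5), 1)
    expect_equal(observed_snv_near_sv(snvs, svs, r),
                 oracle_observed(snvs$chrom, snvs$pos,
                                 c(svs$chrom1, svs$chrom2),
                                 c(svs$pos1, svs$pos2), r))
  }
})

test_that("relative_rate divides observed by expected and rejects zero expectation", {
  expect_equal(relative_rate(200, 100), 2)
  expect_equal(relative_rate(100, 100), 1)
  expect_equal(relative_rate(0, 50), 0)
  expect_error(relative_rate(5, 0), "undefined")
})

test_that("sample_enrichment reports the formula and overlap-aware expectations", {
  a <- tiny_assembly(chr1 = 1e7)
  snvs <- make_snvs("chr1", seq(0, 9.9e6, by = 1e4), a)  # 990 uniform SNVs
  svs <- make_svs("chr1", 5e6, a, pos2 = 5e6 + 10)
  res <- sample_enrichment(snvs, svs, range_bp = 1e5, sample_id = "s1")
  expect_equal(res$expected_near,
               expected_snv_count(nrow(snvs), 1e7, 1, 1e5))
  # both breakpoints 10 bp apart: merged window spans 2e5 + 11 positions
  expect_equal(res$window_bp, 2e5 + 11)
  expect_equal(res$observed_near,
               sum(abs(snvs$pos - 5e6) <= 1e5 | abs(snvs$pos - 5e6 - 10) <= 1e5))
  expect_equal(res$relative_rate, res$observed_near / res$expected_near)
  # breakpoint unit doubles the formula expectation
  res2 <- sample_enrichment(snvs, svs, 1e5, sv_site_unit = "breakpoint")
  expect_equal(res2$expected_near, 2 * res$expected_near)

  # zero SVs: zero expectations, undefined rates, no crash
  res0 <- sample_enrichment(snvs, sv_set(assembly = a), 1e5)
  expect_equal(res0$observed_near, 0L)
  expect_equal(res0$expected_near, 0)
  expect_true(is.na(res0$relative_rate))
  expect_true(is.na(res0$fold_enrichment))
})

test_that("cohort_enrichment_test matches a textbook paired t and handles degeneracy", {
  set.seed(8)
  obs <- rpois(10, 100) + 30
  exp_ <- obs - (rnorm(10, 10, 4))
  res <- data.frame(observed_near = obs, expected_near = exp_,
                    expected_merged = exp_, expected_bg = exp_)
  got <- cohort_enrichment_test(res, mode = "paired_counts")
  d <- obs - exp_
  t_ref <- mean(d) / (sd(d) / sqrt(length(d)))
  p_ref <- 2 * stats::pt(-abs(t_ref), length(d) - 1)
  expect_equal(got$statistic, t_ref, tolerance = 1e-9)
  expect_equal(got$p_value, p_ref, tolerance = 1e-9)

  lr <- cohort_enrichment_test(res, mode = "log_ratio")
  l <- log(obs / exp_)
  t_lr <- mean(l) / (sd(l) / sqrt(length(l)))
  expect_equal(lr$statistic, t_lr, tolerance = 1e-9)

  same <- data.frame(observed_near = c(5, 7, 9),
                     expected_near = c(5, 7, 9),
                     expected_merged = c(5, 7, 9), expected_bg = c(5, 7, 9))
  deg <- cohort_enrichment_test(same)
  expect_true(deg$degenerate)
  expect_equal(deg$statistic, 0)
  expect_equal(deg$p_value, 1)

  expect_error(cohort_enrichment_test(same[1:2, ]), "3 samples")
})

test_that("region_tallies respects half-open intervals and flanks", {
  a <- tiny_assembly(chr1 = 1e6)
  snvs <- make_snvs("chr1", c(1500, 2500), a)
  svs <- make_svs("chr1", 1999, a, pos2 = 2000)
  regions <- data.frame(name = "g1", chrom = "chr1", start = 1000, end = 2000)
  t1 <- region_tallies(regions, snvs, svs)
  expect_equal(t1$n_snv, 1L)
  expect_equal(t1$n_sv_breakpoints, 1L)  # 2000 is exclusive
  expect_true(t1$has_both)

  t2 <- region_tallies(regions, snvs, svs, flank_bp = 1000)
  expect_equal(t2$n_snv, 2L)
  expect_equal(t2$n_sv_breakpoints, 2L)

  empty <- region_tallies(regions[0, ], snvs, svs)
  expect_equal(nrow(empty), 0L)
  bad <- data.frame(name = "g", chrom = "chr1", start = 10, end = 10)
  expect_error(region_tallies(bad, snvs, svs), "exceed")
})
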