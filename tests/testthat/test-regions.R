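test_that("windows tile contigs, keep the partial tail and flag validity", {
  w <- make_windows(c(chrA = 120000), size = 50000, min_snps = 1)
  expect_equal(w$start, c(0, 50000, 100000))
  expect_equal(w$end, c(50000, 100000, 120000))
  expect_equal(w$partial, c(FALSE, FALSE, TRUE))
  expect_equal(sum(w$end - w$start), 120000)

  # validity threshold is >= min_snps: 99 SNPs invalid, 100 valid
  gm99 <- toy_gm(matrix(1L, 99, 2), pos = seq(101L, by = 10L, length.out = 99))
  gm100 <- toy_gm(matrix(1L, 100, 2), pos = seq(101L, by = 10L, length.out = 100))
  w99 <- make_windows(c(chr1 = 50000), 50000, min_snps = 100, gm = gm99)
  w100 <- make_windows(c(chr1 = 50000), 50000, min_snps = 100, gm = gm100)
  expect_false(w99$valid[1])
  expect_true(w100$valid[1])
  expect_equal(w99$n_snps[1], 99L)

  # empty matrix -> all invalid
  empty <- toy_gm(matrix(integer(), 0, 2))
  w0 <- make_windows(c(chr1 = 100000), 50000, min_snps = 1, gm = empty)
  expect_true(all(w0$n_snps == 0L))
  expect_true(all(!w0$valid))

  expect_error(make_windows(c(chrX = 1000), 500, gm = gm99), "missing")
})

test_that("merge_regions unions by gap threshold", {
  rs <- region_set("c", c(0, 55000, 130000), c(10000, 65000, 140000))
  m <- merge_regions(rs, max_gap = 50000)
  expect_equal(m$start, c(0, 130000))
  expect_equal(m$end, c(65000, 140000))
  # max_gap 0 leaves disjoint input unchanged
  expect_equal(merge_regions(rs, 0)$start, rs$start)
  # overlapping regions union regardless of gap
  ov <- region_set("c", c(0, 5000), c(10000, 20000))
  expect_equal(merge_regions(ov, 0)$end, 20000)
  expect_error(merge_regions(rs, -1), "non-negative")
})

test_that("BED write/read round trip is byte stable", {
  rs <- region_set(c("chr2", "chr1", "chr1"), c(100, 0, 500),
                   c(200, 50, 900), label = "x")
  rs$score <- c(0.25, 0.5, 0.75)[order(c("chr2", "chr1", "chr1"),
                                       c(100, 0, 500))]
  p1 <- withr::local_tempfile(fileext = ".bed")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(rs, p1)
  write_bed(read_bed(p1), p2)
  expect_identical(readLines(p1), readLines(p2))
})

test_that("overlap summary counts regions and shared bases", {
  a <- region_set("c", c(0, 20000), c(10000, 30000))
  b_disjoint <- region_set("c", 50000, 60000)
  expect_equal(region_overlap_summary(a, b_disjoint)$n_overlapping, 0L)
  same <- region_overlap_summary(a, a)
  expect_equal(same$n_overlapping, 2L)
  expect_equal(same$fraction_a_overlapped, 1.0)
  part <- region_overlap_summary(region_set("c", 0, 10000),
                                 region_set("c", 5000, 15000))
  expect_equal(part$n_overlapping, 1L)
  expect_equal(part$shared_bp, 5000)
})

test_that("random control regions preserve lengths, reproduce, and are uniform", {
  template <- region_set("chr1", 20000, 30000)
  ctrl <- random_control_regions(c(chr1 = 1e6), template, n_reps = 1000,
                                 seed = 9)
  lens <- vapply(ctrl, function(r) r$end[1] - r$start[1], numeric(1))
  expect_true(all(lens == 10000))
  starts <- vapply(ctrl, function(r) r$start[1], numeric(1))
  # uniform placement: mean start (1e6 - 1e4)/2 within 3 SE
  se <- (1e6 - 1e4) / sqrt(12) / sqrt(1000)
  expect_lt(abs(mean(starts) - 495000), 3 * se)
  ctrl2 <- random_control_regions(c(chr1 = 1e6), template, n_reps = 1000,
                                  seed = 9)
  expect_identical(ctrl, ctrl2)
  # non-overlap within a replicate
  big <- region_set("chr1", c(0, 400000), c(300000, 700000))
  reps <- random_control_regions(c(chr1 = 1e6), big, n_reps = 20, seed = 1)
  for (r in reps) {
    expect_true(r$start[2] >= r$end[1] || r$start[1] >= r$end[2])
  }
})

test_that("complement partitions the contig", {
  rs <- region_set("c", c(100, 500), c(200, 800))
  comp <- complement_regions(rs, c(c = 1000))
  expect_equal(comp$start, c(0, 200, 800))
  expect_equal(comp$end, c(100, 500, 1000))
  expect_equal(sum(comp$end - comp$start) + sum(rs$end - rs$start), 1000)
})
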