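freq_windows <- function(n, L = 1000) {
  make_windows(c(chr1 = L), L, min_snps = 1,
               gm = toy_gm(matrix(1L, n, 1), pos = seq_len(n) * 3L))
}

test_that("trio frequencies count derived alleles and exclude missing groups", {
  d <- cbind(p1a = 0L, p2a = 1L, p2b = 2L, p3a = 1L, og = 0L)
  gm <- toy_gm(d, pos = 11L)
  pm <- c(p1a = "P1g", p2a = "P2g", p2b = "P2g", p3a = "P3g", og = "O")
  fq <- trio_site_freqs(gm, pm, c(P1 = "P1g", P2 = "P2g", P3 = "P3g", O = "O"))
  expect_equal(fq$p2, 0.75)
  expect_equal(fq$p1, 0)
  # group fully missing -> site excluded
  d2 <- rbind(d, c(0L, NA, NA, 1L, 0L))
  gm2 <- toy_gm(d2, pos = c(11L, 22L))
  fq2 <- trio_site_freqs(gm2, pm, c(P1 = "P1g", P2 = "P2g", P3 = "P3g", O = "O"))
  expect_equal(nrow(fq2), 1L)
  expect_error(trio_site_freqs(gm, pm, c(P1 = "P1g", P2 = "P2g", P3 = "P3g")),
               "roles")
})

test_that("window D/fd/fdM match hand values and the site-loop oracle", {
  w <- freq_windows(1)
  fq <- data.frame(chrom = "chr1", pos = 3L, p1 = 0, p2 = 0.5, p3 = 0.5, p4 = 0)
  r <- window_abba_baba(fq, w)
  expect_equal(r$sum_abba, 0.25)
  expect_equal(r$sum_baba, 0)
  expect_equal(r$D, 1)
  expect_equal(r$fd, 1)

  # p1 = p2 everywhere -> D = 0, fdM = 0, fd NaN (numerator 0)
  n <- 6
  fq2 <- data.frame(chrom = "chr1", pos = seq_len(n) * 3L,
                    p1 = rep(0.3, n), p2 = rep(0.3, n),
                    p3 = stats::runif(n), p4 = 0)
  r2 <- window_abba_baba(fq2, freq_windows(n))
  expect_equal(r2$D, 0)
  expect_equal(r2$fdM, 0)
  expect_true(is.nan(r2$fd))

  # excess BABA -> D < 0, fdM < 0, fd NaN
  fq3 <- data.frame(chrom = "chr1", pos = c(3L, 6L),
                    p1 = c(0.9, 0.8), p2 = c(0.1, 0), p3 = c(0.9, 0.7), p4 = 0)
  r3 <- window_abba_baba(fq3, freq_windows(2))
  expect_lt(r3$D, 0)
  expect_lt(r3$fdM, 0)
  expect_true(is.nan(r3$fd))

  # vectorized sums equal the brute-force site loop exactly
  set.seed(99)
  for (i in 1:3) {
    n <- 15
    fqr <- data.frame(chrom = "chr1", pos = seq_len(n) * 3L,
                      p1 = stats::runif(n), p2 = stats::runif(n),
                      p3 = stats::runif(n), p4 = stats::runif(n, 0, 0.1))
    rr <- window_abba_baba(fqr, freq_windows(n))
    or <- oracle_abba_sums(fqr$p1, fqr$p2, fqr$p3, fqr$p4)
    expect_equal(rr$sum_abba, unname(or["abba"]), tolerance = 1e-12)
    expect_equal(rr$sum_baba, unname(or["baba"]), tolerance = 1e-12)
    num <- or["abba"] - or["baba"]
    expect_equal(rr$D, unname(num / (or["abba"] + or["baba"])),
                 tolerance = 1e-12)
    if (num > 0) expect_equal(rr$fd, unname(num / or["dfd"]), tolerance = 1e-12)
    expect_equal(rr$fdM, unname(num / or["dfdm"]), tolerance = 1e-12)
  }
})

test_that("fdM sign agrees with D on valid windows", {
  set.seed(7)
  for (i in 1:20) {
    n <- 10
    fq <- data.frame(chrom = "chr1", pos = seq_len(n) * 3L,
                     p1 = stats::runif(n), p2 = stats::runif(n),
                     p3 = stats::runif(n), p4 = 0)
    r <- window_abba_baba(fq, freq_windows(n))
    if (is.finite(r$D) && is.finite(r$fdM) && r$D != 0) {
      expect_equal(sign(r$fdM), sign(r$D))
    }
  }
})

test_that("jackknife over windows gives a finite standard error", {
  set.seed(13)
  n <- 200
  fq <- data.frame(chrom = "chr1", pos = sort(sample.int(20000L, n)),
                   p1 = stats::runif(n), p2 = stats::runif(n),
                   p3 = stats::runif(n), p4 = 0)
  gm_like <- toy_gm(matrix(1L, n, 1), pos = fq$pos)
  w <- make_windows(c(chr1 = 20000), 1000, min_snps = 1, gm = gm_like)
  r <- window_abba_baba(fq, w)
  jk <- d_jackknife(r)
  expect_true(is.finite(jk$D) && is.finite(jk$se) && jk$se > 0)
  expect_equal(jk$n_blocks, sum(r$valid & r$n_sites_used > 0))
})

test_that("top-quantile region extraction counts and keeps ties", {
  n <- 100
  tr <- data.frame(chrom = "chr1", start = (seq_len(n) - 1) * 1000,
                   end = seq_len(n) * 1000, n_sites_used = 10,
                   sum_abba = 1, sum_baba = 0, D = 1,
                   fd = seq_len(n) / n, fdM = 0.5, valid = TRUE)
  top <- top_quantile_regions(tr, q = 0.05)
  expect_equal(nrow(top), 5L)
  expect_true(all(top$score >= 0.96))
  # ties at the threshold are all included
  tr$fd <- rep(c(0.1, 0.9), each = 50)
  expect_equal(nrow(top_quantile_regions(tr, q = 0.05)), 50L)
  tr$fd <- NaN
  expect_error(top_quantile_regions(tr, 0.05), "no valid windows")
  expect_error(top_quantile_regions(tr, 1.5), "q must be")
})

test_that("gene counts per fd bin follow the overlap rule", {
  tr <- data.frame(chrom = "chr1", start = c(0, 1000), end = c(1000, 2000),
                   n_sites_used = 5, sum_abba = 1, sum_baba = 0,
                   D = 1, fd = c(0.1, 0.6), fdM = 0.5, valid = TRUE)
  genes <- region_set("chr1", c(10, 200, 500, 950), c(50, 300, 600, 1100),
                      label = "gene")
  out <- genes_per_fd_bin(tr, genes, bin_edges = c(0, 0.5, 1))
  # window 1 overlaps 4 genes (one straddles into window 2)
  expect_equal(out$mean_genes[out$bin == "[0,0.5)"], 4)
  expect_equal(out$mean_genes[out$bin == "[0.5,1]"], 1)
  out2 <- genes_per_fd_bin(tr, genes, bin_edges = c(0, 0.2, 0.5, 1))
  expect_true(is.nan(out2$mean_genes[out2$n_windows == 0]))
})

test_that("fbranch rejects donors below the focal branch and needs a matching tree", {
  d <- cbind(w1 = 1L, w2 = 1L, t1 = 0L, m1 = 0L, e1 = 1L, o1 = 0L)
  gm <- toy_gm(rbind(d, d, d), pos = c(5L, 15L, 25L))
  pm <- c(w1 = "wine", w2 = "wine", t1 = "table", m1 = "ME1", e1 = "EU",
          o1 = "OUT")
  fb <- fbranch(gm, pm, "(((wine,table),ME1),EU);", "OUT")
  expect_true(is.nan(fb$fb["wine", "wine"]))        # donor below branch
  expect_true(is.nan(fb$fb["table,wine", "wine"]))
  expect_true(is.finite(fb$fb["wine", "EU"]))       # valid cell
  expect_true(all(fb$fb[is.finite(fb$fb)] >= 0))    # floored at zero
  expect_error(fbranch(gm, pm, "(((wine,table),badgroup),EU);", "OUT"),
               "missing from popmap")
})
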