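popmap2 <- function(gm, split_at) {
  stats::setNames(ifelse(seq_along(gm$samples) <= split_at, "A", "B"),
                  gm$samples)
}

test_that("sample heterozygosity follows its definition and is order invariant", {
  d <- matrix(0L, 10, 2)
  d[c(1, 4, 7), 1] <- 1L      # 3 het of 10 sites
  d[2, 2] <- 2L               # hom-derived only
  colnames(d) <- c("het3", "hom")
  gm <- toy_gm(d)
  h <- sample_heterozygosity(gm)
  expect_equal(unname(h["het3"]), 0.3)
  expect_equal(unname(h["hom"]), 0.0)
  perm <- sample(10)
  gm_perm <- toy_gm(d[perm, ], pos = seq_len(10) * 10L)
  expect_equal(sample_heterozygosity(gm_perm), h)
  expect_error(sample_heterozygosity(toy_gm(matrix(integer(), 0, 1))),
               "no sites")
})

test_that("window pi matches hand value and haplotype-pair brute force", {
  # 2 diploids, one site with derived count 2 -> 2*0.5*0.5*4/3 = 2/3
  d <- matrix(c(1L, 1L), 1, 2)
  gm <- toy_gm(d, pos = 500L)
  w <- make_windows(c(chr1 = 1000), 1000, min_snps = 1, gm = gm)
  pm <- stats::setNames(rep("A", 2), gm$samples)
  res <- window_pi(gm, pm, "A", w)
  expect_equal(res$pi, 2 / 3 / 1000, tolerance = 1e-12)

  # monomorphic window -> 0; doubling window length halves pi
  gm0 <- toy_gm(matrix(2L, 3, 2), pos = c(10L, 20L, 30L))
  w0 <- make_windows(c(chr1 = 1000), 1000, min_snps = 1, gm = gm0)
  expect_equal(window_pi(gm0, stats::setNames(rep("A", 2), gm0$samples),
                         "A", w0)$pi, 0)
  w2 <- make_windows(c(chr1 = 2000), 2000, min_snps = 1, gm = gm)
  expect_equal(window_pi(gm, pm, "A", w2)$pi, res$pi / 2)

  # brute-force oracle on random matrices with missingness (<= 8 haplotypes)
  for (seed in 1:3) {
    gmr <- random_gm(15, 4, seed = seed, miss = 0.1)
    pmr <- stats::setNames(rep("A", 4), gmr$samples)
    wr <- make_windows(c(chr1 = 1000), 1000, min_snps = 1, gm = gmr)
    expected <- sum(vapply(seq_len(15), function(i)
      oracle_site_pi(gmr$dosage[i, ]), numeric(1)), na.rm = TRUE) / 1000
    expect_equal(window_pi(gmr, pmr, "A", wr)$pi, expected, tolerance = 1e-12)
  }
})

test_that("window dxy matches definition, symmetry and brute force", {
  # fixed difference at one site in a 100-bp window
  d <- cbind(A1 = 0L, A2 = 0L, B1 = 2L, B2 = 2L)
  gm <- toy_gm(d, pos = 50L)
  pm <- c(A1 = "A", A2 = "A", B1 = "B", B2 = "B")
  w <- make_windows(c(chr1 = 100), 100, min_snps = 1, gm = gm)
  expect_equal(window_dxy(gm, pm, "A", "B", w)$dxy, 0.01)

  # identical groups: dxy_difference(A vs B, A vs B) = 0
  dd <- dxy_difference(window_dxy(gm, pm, "A", "B", w),
                       window_dxy(gm, pm, "A", "B", w))
  expect_equal(dd$dxy_diff, 0)
  expect_equal(dxy_difference(data.frame(chrom = "c", start = 0, end = 1,
                                         dxy = 0.003),
                              data.frame(chrom = "c", start = 0, end = 1,
                                         dxy = 0.005))$dxy_diff, -0.002)

  gmr <- random_gm(12, 6, seed = 8, miss = 0.1)
  pmr <- popmap2(gmr, 3)
  wr <- make_windows(c(chr1 = 1000), 1000, min_snps = 1, gm = gmr)
  expected <- sum(vapply(seq_len(12), function(i)
    oracle_site_dxy(gmr$dosage[i, 1:3], gmr$dosage[i, 4:6]),
    numeric(1)), na.rm = TRUE) / 1000
  expect_equal(window_dxy(gmr, pmr, "A", "B", wr)$dxy, expected,
               tolerance = 1e-12)
})

test_that("Hudson FST matches hand evaluation and ratio-of-sums oracle", {
  # single site pA = 0.8, pB = 0.2, 10 haplotypes each
  d <- cbind(matrix(c(2L, 2L, 2L, 1L, 1L), 1, 5),
             matrix(c(0L, 0L, 0L, 1L, 1L), 1, 5))
  colnames(d) <- paste0("S", 1:10)
  gm <- toy_gm(d, pos = 7L)
  pm <- popmap2(gm, 5)
  w <- make_windows(c(chr1 = 100), 100, min_snps = 1, gm = gm)
  expect_equal(window_fst(gm, pm, "A", "B", w)$fst,
               (0.36 - 2 * 0.16 / 9) / 0.68, tolerance = 1e-12)
  expect_equal(window_fst(gm, pm, "A", "B", w)$fst, 0.4771, tolerance = 1e-4)

  # pA = pB = 0.5 with 10 haplotypes: small negative estimate, as computed
  d2 <- cbind(matrix(1L, 1, 5), matrix(1L, 1, 5))
  colnames(d2) <- paste0("S", 1:10)
  gm2 <- toy_gm(d2, pos = 7L)
  fst2 <- window_fst(gm2, popmap2(gm2, 5), "A", "B", w)$fst
  expect_equal(fst2, (0 - 2 * 0.25 / 9) / 0.5, tolerance = 1e-12)
  expect_lt(fst2, 0)

  # ratio-of-sums equals per-site oracle sums on random input
  gmr <- random_gm(20, 8, seed = 5, miss = 0.05)
  pmr <- popmap2(gmr, 4)
  wr <- make_windows(c(chr1 = 1000), 1000, min_snps = 1, gm = gmr)
  comp <- vapply(seq_len(20), function(i) {
    da <- gmr$dosage[i, 1:4]; db <- gmr$dosage[i, 5:8]
    na <- 2 * sum(!is.na(da)); nb <- 2 * sum(!is.na(db))
    if (na < 2 || nb < 2) return(c(num = NA, den = NA))
    oracle_hudson(sum(da, na.rm = TRUE) / na, na,
                  sum(db, na.rm = TRUE) / nb, nb)
  }, numeric(2))
  expect_equal(window_fst(gmr, pmr, "A", "B", wr)$fst,
               sum(comp["num", ], na.rm = TRUE) /
                 sum(comp["den", ], na.rm = TRUE),
               tolerance = 1e-12)
})

test_that("PBS transforms and symmetries hold", {
  r <- pbs(0.1, 0.1, 0.0)
  expect_equal(r$pbs, (-log(0.9) - log(0.9)) / 2, tolerance = 1e-12)
  expect_equal(r$pbs, 0.10536, tolerance = 1e-4)
  expect_equal(pbs(0, 0, 0)$pbs, 0)
  # symmetric under swap of the two non-focal branches
  expect_equal(pbs(0.3, 0.1, 0.2)$pbs, pbs(0.1, 0.3, 0.2)$pbs)
  # star topology: equal pairwise FST -> identical PBS for every focal choice
  expect_equal(pbs(0.2, 0.2, 0.2)$pbs, pbs(0.2, 0.2, 0.2)$pbs)
  expect_true(pbs(1, 0.5, 0.5)$flagged)
})

test_that("PI_HAT recovers self, unrelated and parent-offspring relationships", {
  set.seed(42)
  n_sites <- 2000
  p <- stats::runif(n_sites, 0.1, 0.9)
  # cohort of 20 unrelated + duplicate of S1 + child of S1 x S2
  draw <- function() matrix(stats::rbinom(n_sites * 2, 1, p), n_sites, 2)
  genos <- replicate(20, rowSums(draw()))
  gam <- function(g) {        # transmit one allele per site from genotype g
    het <- g == 1L
    out <- as.integer(g == 2L)
    out[het] <- stats::rbinom(sum(het), 1, 0.5)
    out
  }
  parents <- list(draw(), draw())
  g1 <- rowSums(parents[[1]]); g2 <- rowSums(parents[[2]])
  child <- gam(g1) + gam(g2)
  d <- cbind(genos, g1, g2, dup = g1, child = child)
  colnames(d) <- c(paste0("U", 1:20), "P1", "P2", "DUP", "CH")
  gm <- toy_gm(d, pos = seq_len(n_sites) * 3L)
  res <- pairwise_pi_hat(gm, pairs = data.frame(
    id1 = c("P1", "U1", "P1"),
    id2 = c("DUP", "U2", "CH")))
  expect_equal(res$pi_hat[res$id2 == "DUP"], 1, tolerance = 1e-6)
  expect_lt(res$pi_hat[res$id2 == "U2"], 0.1)
  expect_equal(res$pi_hat[res$id2 == "CH"], 0.5, tolerance = 0.1)
  expect_false(any(res$low_confidence))
})
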