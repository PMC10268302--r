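load_fixture <- function() {
  # 8 sites on a 1000-bp contig: 4 dSNP, 3 sSNP, 1 unclassified
  d <- cbind(ind = c(1L, 1L, 2L, 0L, 1L, 2L, 0L, 1L),
             ref = c(0L, 0L, 0L, 0L, 0L, 0L, 0L, 0L))
  gm <- toy_gm(d, pos = c(101L, 201L, 301L, 401L, 501L, 601L, 701L, 801L))
  effects <- data.frame(chrom = "chr1",
                        pos = c(101L, 201L, 301L, 401L, 501L, 601L, 701L),
                        class = c("dSNP", "dSNP", "dSNP", "dSNP",
                                  "sSNP", "sSNP", "sSNP"))
  list(gm = gm, effects = effects)
}

test_that("per-individual load counts and the three load models", {
  fx <- load_fixture()
  strata <- region_set("chr1", 0, 1000, label = "all")
  lt <- load_per_individual(fx$gm, fx$effects, strata)
  ind <- lt[lt$sample == "ind", ]
  # dSNP genotypes {0/1, 0/1, 1/1, 0/0}: het 2, recessive 1, additive 4
  expect_equal(ind$het_load, 2)
  expect_equal(ind$recessive_load, 1)
  expect_equal(ind$additive_load, 4)
  # sSNP genotypes {0/1, 1/1, 0/0}: additive 3; ratio 4/3
  expect_equal(ind$additive_s, 3)
  expect_equal(ind$ratio_ds, 4 / 3)
  # all-reference individual: zero loads, NaN ratio
  ref <- lt[lt$sample == "ref", ]
  expect_equal(ref$additive_load, 0)
  expect_true(is.nan(ref$ratio_ds))
  # additive identity on random data
  gmr <- random_gm(30, 5, seed = 21)
  effr <- data.frame(chrom = "chr1", pos = gmr$pos,
                     class = rep(c("dSNP", "sSNP", "SV"), length.out = 30))
  ltr <- load_per_individual(gmr, effr,
                             region_set("chr1", 0, 1200, label = "g"))
  expect_equal(ltr$additive_load, ltr$het_load + 2 * ltr$recessive_load)
})

test_that("class density over a union is the length-weighted stratum mean", {
  gmr <- random_gm(40, 4, seed = 33)
  effr <- data.frame(chrom = "chr1", pos = gmr$pos, class = "dSNP")
  strata <- region_set("chr1", c(0, 600), c(600, 1100),
                       label = c("s1", "s2"))
  un <- region_set("chr1", 0, 1100, label = "union")
  lt <- load_per_individual(gmr, effr, as_region_set(
    rbind(strata[, c("chrom", "start", "end", "label")],
          un[, c("chrom", "start", "end", "label")])))
  for (smp in gmr$samples) {
    x <- lt[lt$sample == smp, ]
    lhs <- x$het_density[x$stratum == "union"]
    rhs <- (x$het_density[x$stratum == "s1"] * 600 +
              x$het_density[x$stratum == "s2"] * 500) / 1100
    expect_equal(lhs, rhs, tolerance = 1e-12)
  }
})

test_that("unfolded SFS bins by derived count and guards degenerate input", {
  # one segregating dSNP site at derived count 2 among 10 haplotypes
  d <- matrix(0L, 3, 5)
  d[1, 1] <- 2L                      # count 2 of 10
  d[2, ] <- 0L                       # monomorphic (excluded)
  d[3, 2] <- 1L                      # count 1
  colnames(d) <- paste0("S", 1:5)
  gm <- toy_gm(d, pos = c(10L, 20L, 30L))
  eff <- data.frame(chrom = "chr1", pos = c(10L, 20L, 30L), class = "dSNP")
  pm <- stats::setNames(rep("G", 5), gm$samples)
  sfs <- sfs_by_class(gm, eff, region_set("chr1", 0, 100, label = "s"),
                      pm, "G", "dSNP")
  expect_equal(sfs$n_hap, 10)
  expect_equal(sfs$counts[2], 1L)
  expect_equal(sum(sfs$proportions), 1)
  eff1 <- eff[1, ]
  expect_error(sfs_by_class(gm, eff1, region_set("chr1", 0, 100, label = "s"),
                            pm, "G", "dSNP"), "fewer than 2")
})

test_that("signed-rank SFS comparison handles ties and detects shifts", {
  s <- c(0.4, 0.25, 0.15, 0.1, 0.06, 0.04)
  same <- compare_sfs(s, s)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # shift mass one bin left relative to the copy: a[i] = s[i+1]
  shifted <- c(s[-1], 0)
  cmp <- compare_sfs(shifted, s)
  expect_lt(cmp$statistic, 0)
  expect_equal(cmp$direction, -1)
})

test_that("introgressed allele spectrum follows the operational definition", {
  # site 1: donor 0.5, refs absent, recipients all het
  # site 2: present in a reference group -> excluded
  # site 3: recipients {1/1, 0/0}
  d <- rbind(c(1L, 1L, 0L, 0L, 1L, 1L, 0L),
             c(1L, 1L, 1L, 0L, 1L, 0L, 0L),
             c(2L, 0L, 0L, 0L, 2L, 0L, 0L))
  colnames(d) <- c("d1", "d2", "r1", "r2", "w1", "w2", "og")
  gm <- toy_gm(d, pos = c(10L, 20L, 30L))
  pm <- c(d1 = "EU", d2 = "EU", r1 = "ME", r2 = "ME",
          w1 = "wine", w2 = "wine", og = "OUT")
  spec <- introgressed_allele_spectrum(gm, pm, "EU", "ME", "wine",
                                       region_set("chr1", 0, 100,
                                                  label = "intro"))
  expect_equal(nrow(spec$alleles), 2L)
  a1 <- spec$alleles[spec$alleles$pos == 10, ]
  expect_equal(a1$carrier_fraction, 1.0)
  expect_equal(a1$recipient_freq, 0.5)
  expect_equal(a1$het_share, 1.0)
  a3 <- spec$alleles[spec$alleles$pos == 30, ]
  expect_equal(a3$carrier_fraction, 0.5)
  expect_equal(a3$recipient_freq, 0.5)
  expect_equal(a3$het_share, 0)
  expect_warning(
    introgressed_allele_spectrum(gm, pm, "EU", "ME", "wine",
                                 region_set("chr1", 0, 100, label = "x"),
                                 donor_min = 0.99),
    "no introgressed candidate")
})

test_that("random-control densities bracket the genome-wide density", {
  # dSNPs placed uniformly: control regions should straddle the global rate
  set.seed(77)
  n <- 400
  pos <- sort(sample.int(100000L, n))
  d <- matrix(sample(0:2, n * 4, replace = TRUE, prob = c(0.5, 0.3, 0.2)),
              n, 4)
  colnames(d) <- paste0("S", 1:4)
  gm <- toy_gm(d, pos = pos)
  eff <- data.frame(chrom = "chr1", pos = pos, class = "dSNP")
  template <- region_set("chr1", 20000, 30000, label = "t")
  ctrls <- random_control_regions(c(chr1 = 100000), template,
                                  n_reps = 100, seed = 5)
  dens <- vapply(ctrls, function(cr) {
    cr$label <- "c"
    mean(load_per_individual(gm, eff, cr)$het_density)
  }, numeric(1))
  global <- mean(load_per_individual(
    gm, eff, region_set("chr1", 0, 100000, label = "g"))$het_density)
  expect_gt(global, stats::quantile(dens, 0.025))
  expect_lt(global, stats::quantile(dens, 0.975))
})
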