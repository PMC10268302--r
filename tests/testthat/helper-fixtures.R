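# Shared fixtures and independent brute-force oracles.

# Deterministic toy genotype matrix.
toy_gm <- function(dosage, chrom = NULL, pos = NULL, coded = "derived") {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  genotype_matrix(chrom = chrom %||% rep("chr1", n),
                  pos = pos %||% (seq_len(n) * 10L),
                  ref = rep("A", n), alt = rep("T", n),
                  dosage = dosage, coded = coded)
}
`%||%` <- function(a, b) if (is.null(a)) b else a

# Random toy matrix under a fixed local seed.
random_gm <- function(n_sites, n_samples, seed, miss = 0) {
  set.seed(seed)
  d <- matrix(sample(0:2, n_sites * n_samples, replace = TRUE),
              n_sites, n_samples)
  if (miss > 0) d[sample(length(d), round(miss * length(d)))] <- NA
  colnames(d) <- paste0("S", seq_len(n_samples))
  toy_gm(d, pos = sort(sample.int(1000L, n_sites)))
}

# A small text VCF: 1 multiallelic, 1 indel, 3 biallelic SNP records.
write_toy_vcf <- function(path) {
  lines <- c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", "A", "B", "C"), collapse = "\t"),
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1\t1/1",
    "chr1\t200\t.\tG\tA,C\t.\tPASS\t.\tGT\t0/1\t0/2\t1/1",   # multiallelic
    "chr1\t300\t.\tC\tCTT\t.\tPASS\t.\tGT\t0/0\t0/1\t0/0",   # indel
    "chr1\t400\t.\tT\tG\t.\tPASS\t.\tGT\t./.\t1/1\t0/1",
    "chr2\t150\t.\tC\tG\t.\tPASS\t.\tGT\t0/1\t0/0\t0/0")
  writeLines(lines, path)
  path
}

# Fast synthetic scenario for mechanics tests (not the study-scale default).
fast_scenario <- function(seed = 1, ...) {
  scenario_config(n_sites = 800, N_anc = 50, N_eu = 18, N_me = 40,
                  N_cult = 36, t_burn = 15, t1 = 20, t2 = 8, t3 = 6,
                  t4_pre = 3, t4_backcross = 4, t4_clonal = 4,
                  n_sample = c(ME1 = 6, ME2 = 6, EU = 6, table = 8, wine = 8),
                  seed = seed, ...)
}

## ---- brute-force oracles ----

# Within-group pi per site: fraction of unequal haplotype pairs among
# non-missing haplotypes (dosage 1 contributes one of each allele).
oracle_site_pi <- function(dosages) {
  haps <- unlist(lapply(dosages[!is.na(dosages)], function(d)
    switch(as.character(d), `0` = c(0, 0), `1` = c(0, 1), `2` = c(1, 1))))
  n <- length(haps)
  if (n < 2) return(NaN)
  pairs <- utils::combn(n, 2)
  mean(haps[pairs[1, ]] != haps[pairs[2, ]])
}

# Between-group dxy per site: fraction of unequal cross-group haplotype pairs.
oracle_site_dxy <- function(dos_a, dos_b) {
  expand <- function(d) unlist(lapply(d[!is.na(d)], function(x)
    switch(as.character(x), `0` = c(0, 0), `1` = c(0, 1), `2` = c(1, 1))))
  ha <- expand(dos_a); hb <- expand(dos_b)
  if (!length(ha) || !length(hb)) return(NaN)
  mean(outer(ha, hb, `!=`))
}

# Hudson FST per-site components evaluated site by site.
oracle_hudson <- function(pa, na, pb, nb) {
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  c(num = num, den = den)
}

# ABBA-BABA site loop oracle returning window sums.
oracle_abba_sums <- function(p1, p2, p3, p4) {
  abba <- baba <- dfd <- dfdm <- 0
  for (i in seq_along(p1)) {
    abba <- abba + (1 - p1[i]) * p2[i] * p3[i] * (1 - p4[i])
    baba <- baba + p1[i] * (1 - p2[i]) * p3[i] * (1 - p4[i])
    pd <- max(p2[i], p3[i])
    dfd <- dfd + ((1 - p1[i]) * pd * pd * (1 - p4[i]) -
                    p1[i] * (1 - pd) * pd * (1 - p4[i]))
    if (p2[i] >= p1[i]) {
      dfdm <- dfdm + ((1 - p1[i]) * pd * pd * (1 - p4[i]) -
                        p1[i] * (1 - pd) * pd * (1 - p4[i]))
    } else {
      pd1 <- max(p1[i], p3[i])
      dfdm <- dfdm - ((1 - pd1) * p2[i] * pd1 * (1 - p4[i]) -
                        pd1 * (1 - p2[i]) * pd1 * (1 - p4[i]))
    }
  }
  c(abba = abba, baba = baba, dfd = dfd, dfdm = dfdm)
}
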