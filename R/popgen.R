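## Windowed diversity and divergence statistics.
##
## pi and Dxy are normalized by full window length in bp, treating positions
## without a SNP record as invariant; this reproduces per-bp magnitudes from
## SNP-only input.  Statistics are NaN in windows flagged invalid so that
## downstream quantile selection skips them.

#' Per-sample heterozygosity
#'
#' Fraction of retained SNP sites at which a sample is heterozygous.
#'
#' @param gm A [genotype_matrix()].
#' @param denominator `"all_sites"` (default): divide by the number of
#'   retained SNP sites; `"non_missing"`: divide by the sample's non-missing
#'   call count.
#' @return Named numeric vector, one ratio per sample.
#' @export
sample_heterozygosity <- function(gm, denominator = c("all_sites", "non_missing")) {
  denominator <- match.arg(denominator)
  if (n_sites(gm) == 0L) stopf("genotype matrix has no sites")
  het <- colSums(gm$dosage == 1L, na.rm = TRUE)
  den <- switch(denominator,
                all_sites = rep(n_sites(gm), length(gm$samples)),
                non_missing = colSums(!is.na(gm$dosage)))
  stats::setNames(het / den, gm$samples)
}

# Per-site unbiased within-group mean pairwise difference:
# 2 p (1-p) n/(n-1) over the n non-missing haplotypes.  NaN where n < 2.
site_pi <- function(p, n_hap) {
  out <- 2 * p * (1 - p) * n_hap / (n_hap - 1)
  out[n_hap < 2L] <- NaN
  out
}

# Sum per-site values into windows; NaN for invalid windows, excluding
# NA/NaN site values from the sums.
window_sum <- function(values, widx, windows) {
  out <- rep(NaN, nrow(windows))
  ok <- !is.na(widx) & !is.na(values)
  if (any(ok)) {
    s <- tapply(values[ok], widx[ok], sum)
    out[as.integer(names(s))] <- as.numeric(s)
    zero <- setdiff(seq_len(nrow(windows)), as.integer(names(s)))
    out[zero] <- 0
  } else {
    out[] <- 0
  }
  out[!windows$valid] <- NaN
  out
}

#' Windowed nucleotide diversity (pi)
#'
#' Per site, the unbiased mean pairwise difference among the group's
#' non-missing haplotypes, `2p(1-p) n/(n-1)`; per window, the site sum
#' divided by window length in bp.
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Named character vector (`sample -> group`).
#' @param group Group label.
#' @param windows Windows from [make_windows()].
#' @return Data.frame: window coordinates, `n_sites`, `pi`.
#' @export
window_pi <- function(gm, popmap, group, windows) {
  smp <- group_samples(gm, popmap, group)
  fr <- allele_freq(gm, smp)
  widx <- site_region_index(gm, windows)
  val <- window_sum(site_pi(fr$p, fr$n_hap), widx, windows) /
    (windows$end - windows$start)
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             n_snps = windows$n_snps, pi = val)
}

#' Windowed absolute divergence (Dxy) and the Dxy-difference contrast
#'
#' Per site `pA(1-pB) + pB(1-pA)`; per window, the site sum divided by window
#' length in bp.  `dxy_difference()` subtracts two such tables elementwise
#' over shared windows — the contrast used to compare a recipient/donor pair
#' against a non-recipient/donor pair (negative values mean the first pair is
#' the more similar one).
#'
#' @param gm A [genotype_matrix()].
#' @param popmap Named character vector (`sample -> group`).
#' @param group_a,group_b Group labels.
#' @param windows Windows from [make_windows()].
#' @return Data.frame: window coordinates, `n_sites`, `dxy`.
#' @export
window_dxy <- function(gm, popmap, group_a, group_b, windows) {
  fa <- allele_freq(gm, group_samples(gm, popmap, group_a))
  fb <- allele_freq(gm, group_samples(gm, popmap, group_b))
  site <- fa$p * (1 - fb$p) + fb$p * (1 - fa$p)
  site[fa$n_hap == 0L | fb$n_hap == 0L] <- NaN
  widx <- site_region_index(gm, windows)
  val <- window_sum(site, widx, windows) / (windows$end - windows$start)
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             n_snps = windows$n_snps, dxy = val)
}

#' @rdname window_dxy
#' @param dxy_a,dxy_b Outputs of `window_dxy()` over the same window set.
#' @export
dxy_difference <- function(dxy_a, dxy_b) {
  if (nrow(dxy_a) != nrow(dxy_b) ||
      any(dxy_a$chrom != dxy_b$chrom | dxy_a$start != dxy_b$start |
          dxy_a$end != dxy_b$end))
    stopf("dxy tables computed over different window sets")
  data.frame(chrom = dxy_a$chrom, start = dxy_a$start, end = dxy_a$end,
             dxy_diff = dxy_a$dxy - dxy_b$dxy)
}

# Per-site Hudson FST numerator and denominator components.
hudson_components <- function(pa, na, pb, nb) {
  num <- (pa - pb)^2 - pa * (1 - pa) / (na - 1) - pb * (1 - pb) / (nb - 1)
  den <- pa * (1 - pb) + pb * (1 - pa)
  bad <- na < 2L | nb < 2L
  num[bad] <- NaN
  den[bad] <- NaN
  list(num = num, den = den)
}

#' Windowed Hudson FST
#'
#' Hudson's estimator as a ratio of sums over sites:
#' `sum[(pA-pB)^2 - pA(1-pA)/(nA-1) - pB(1-pB)/(nB-1)] / sum[pA(1-pB)+pB(1-pA)]`
#' with `nA`, `nB` the non-missing haplotype counts.  Ratio-of-sums is robust
#' to unequal sample sizes and low-information sites; a slightly negative
#' estimate is reported as computed.
#'
#' @inheritParams window_dxy
#' @return Data.frame: window coordinates, `n_sites`, `fst`.  `NaN` where the
#'   denominator sum is zero or the window is invalid.
#' @export
window_fst <- function(gm, popmap, group_a, group_b, windows) {
  fa <- allele_freq(gm, group_samples(gm, popmap, group_a))
  fb <- allele_freq(gm, group_samples(gm, popmap, group_b))
  hc <- hudson_components(fa$p, fa$n_hap, fb$p, fb$n_hap)
  widx <- site_region_index(gm, windows)
  num <- window_sum(hc$num, widx, windows)
  den <- window_sum(hc$den, widx, windows)
  fst <- num / den
  fst[is.finite(den) & den == 0] <- NaN
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             n_snps = windows$n_snps, fst = fst)
}

#' Genome-wide Hudson FST
#'
#' Same estimator as [window_fst()] with the ratio of sums taken over all
#' sites.
#'
#' @inheritParams window_dxy
#' @return A single FST value.
#' @export
global_fst <- function(gm, popmap, group_a, group_b) {
  fa <- allele_freq(gm, group_samples(gm, popmap, group_a))
  fb <- allele_freq(gm, group_samples(gm, popmap, group_b))
  hc <- hudson_components(fa$p, fa$n_hap, fb$p, fb$n_hap)
  sum(hc$num, na.rm = TRUE) / sum(hc$den, na.rm = TRUE)
}

#' Population branch statistic
#'
#' Transforms pairwise FST into branch lengths `T = -log(1 - FST)` and
#' reports the focal branch length
#' `PBS = (T_focal_b + T_focal_c - T_b_c) / 2`, highlighting allele-frequency
#' shifts specific to the focal lineage.  Inputs are vectors (e.g. per
#' window); windows with any FST >= 1 give an infinite transform and are
#' flagged.
#'
#' @param fst_focal_b,fst_focal_c FST between the focal group and the two
#'   reference groups.
#' @param fst_b_c FST between the two reference groups.
#' @return Data.frame with `pbs`, the three `T` transforms, and `flagged`
#'   (non-finite transform).
#' @export
pbs <- function(fst_focal_b, fst_focal_c, fst_b_c) {
  t_fb <- -log(1 - fst_focal_b)
  t_fc <- -log(1 - fst_focal_c)
  t_bc <- -log(1 - fst_b_c)
  val <- (t_fb + t_fc - t_bc) / 2
  flagged <- !is.finite(t_fb) | !is.finite(t_fc) | !is.finite(t_bc)
  data.frame(pbs = val, t_focal_b = t_fb, t_focal_c = t_fc, t_b_c = t_bc,
             flagged = flagged)
}

#' Windowed PBS for a focal group
#'
#' Convenience wrapper computing the three pairwise [window_fst()] tables and
#' the per-window [pbs()].
#'
#' @inheritParams window_dxy
#' @param focal,ref_b,ref_c Group labels; `focal` is the branch being scanned.
#' @return Data.frame: window coordinates, `pbs`, component FST values,
#'   `flagged`.
#' @export
window_pbs <- function(gm, popmap, focal, ref_b, ref_c, windows) {
  f_ab <- window_fst(gm, popmap, focal, ref_b, windows)$fst
  f_ac <- window_fst(gm, popmap, focal, ref_c, windows)$fst
  f_bc <- window_fst(gm, popmap, ref_b, ref_c, windows)$fst
  res <- pbs(f_ab, f_ac, f_bc)
  cbind(data.frame(chrom = windows$chrom, start = windows$start,
                   end = windows$end, n_snps = windows$n_snps),
        res,
        data.frame(fst_focal_b = f_ab, fst_focal_c = f_ac, fst_b_c = f_bc))
}
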