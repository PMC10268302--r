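## Deleterious-load accounting stratified by region class (introgressed,
## background, random controls), plus site-frequency-spectrum machinery for
## effect classes and the introgressed-allele spectrum.

#' Read / write a variant effect-class table
#'
#' TSV with header columns `chrom`, `pos`, `class`; classes are from the
#' closed vocabulary `dSNP` (putatively deleterious), `sSNP` (synonymous,
#' neutral proxy) and `SV` (structural variant coded as a biallelic
#' presence/absence record).
#'
#' @param path Path to the TSV.
#' @return Data.frame with `chrom`, `pos`, `class`.
#' @export
read_effects <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  validate_effects(tb)
}

validate_effects <- function(tb) {
  if (!all(c("chrom", "pos", "class") %in% names(tb)))
    stopf("effect table needs columns chrom, pos, class")
  bad <- setdiff(unique(tb$class), c("dSNP", "sSNP", "SV"))
  if (length(bad))
    stopf("unknown effect classes: %s", paste(bad, collapse = ", "))
  key <- paste(tb$chrom, tb$pos)
  if (anyDuplicated(key)) stopf("duplicate sites in effect table")
  tb
}

#' @rdname read_effects
#' @param effects Data.frame with `chrom`, `pos`, `class`.
#' @export
write_effects <- function(effects, path) {
  utils::write.table(validate_effects(effects), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Effect class per gm site (NA where unclassified).
site_classes <- function(gm, effects) {
  validate_effects(effects)
  m <- match(paste(gm$chrom, gm$pos), paste(effects$chrom, effects$pos))
  effects$class[m]
}

#' Per-individual load counts by effect class and region stratum
#'
#' For every individual and every stratum (one label of `strata`), counts
#' heterozygous and homozygous-derived dSNP and sSNP genotypes and derives
#' the three load models: heterozygous load (`n_het_d`), recessive load
#' (`n_hom_d`, homozygous-derived dSNPs only) and additive load
#' (`n_het_d + 2 * n_hom_d`).  `ratio_ds` is the ratio of additive dSNP to
#' additive sSNP allele counts (a site-count variant is available via
#' `ratio_mode = "sites"`).  Densities divide counts by stratum length.
#'
#' @param gm A [genotype_matrix()] (polarized if classes refer to derived
#'   alleles).
#' @param effects Effect-class table (see [read_effects()]).
#' @param strata A [region_set()] whose `label` column distinguishes strata.
#' @param ratio_mode `"additive"` (allele counts, default) or `"sites"`
#'   (segregating-site counts) for `ratio_ds`.
#' @return Data.frame: one row per sample x stratum with counts, loads,
#'   densities per bp and `ratio_ds`.
#' @export
load_per_individual <- function(gm, effects, strata,
                                ratio_mode = c("additive", "sites")) {
  ratio_mode <- match.arg(ratio_mode)
  cls <- site_classes(gm, effects)
  out <- list()
  for (lab in unique(strata$label)) {
    rs <- strata[strata$label == lab, ]
    widx <- site_region_index(gm, rs)
    inside <- !is.na(widx)
    bp <- sum(rs$end - rs$start)
    d_mask <- inside & !is.na(cls) & cls == "dSNP"
    s_mask <- inside & !is.na(cls) & cls == "sSNP"
    if (!any(d_mask | s_mask))
      warning(sprintf("stratum '%s' contains no classified sites", lab))
    dd <- gm$dosage[d_mask, , drop = FALSE]
    ds <- gm$dosage[s_mask, , drop = FALSE]
    n_het_d <- colSums(dd == 1L, na.rm = TRUE)
    n_hom_d <- colSums(dd == 2L, na.rm = TRUE)
    n_het_s <- colSums(ds == 1L, na.rm = TRUE)
    n_hom_s <- colSums(ds == 2L, na.rm = TRUE)
    additive_d <- n_het_d + 2L * n_hom_d
    additive_s <- n_het_s + 2L * n_hom_s
    ratio <- switch(ratio_mode,
                    additive = additive_d / additive_s,
                    sites = (n_het_d + n_hom_d) / (n_het_s + n_hom_s))
    ratio[!is.finite(ratio)] <- NaN
    classified <- any(d_mask | s_mask)
    dens <- function(x) if (classified) x / bp else rep(NaN, length(x))
    out[[lab]] <- data.frame(
      sample = gm$samples, stratum = lab,
      n_het_d = n_het_d, n_hom_d = n_hom_d,
      n_het_s = n_het_s, n_hom_s = n_hom_s,
      het_load = n_het_d, recessive_load = n_hom_d, additive_load = additive_d,
      additive_s = additive_s, ratio_ds = ratio,
      stratum_bp = bp,
      het_density = dens(n_het_d), recessive_density = dens(n_hom_d),
      additive_density = dens(additive_d),
      row.names = NULL)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Density-ratio summary between two strata
#'
#' Group-level ratio of per-bp heterozygous/recessive/additive dSNP densities
#' between two strata of a [load_per_individual()] table (mean count over
#' individuals divided by stratum length).
#'
#' @param load_table Output of [load_per_individual()].
#' @param stratum_a,stratum_b Stratum labels (numerator, denominator).
#' @return Named numeric vector: `het_ratio`, `recessive_ratio`,
#'   `additive_ratio`.
#' @export
load_density_ratio <- function(load_table, stratum_a, stratum_b) {
  one <- function(lab) {
    x <- load_table[load_table$stratum == lab, ]
    if (!nrow(x)) stopf("stratum '%s' not in load table", lab)
    c(het = mean(x$het_density), rec = mean(x$recessive_density),
      add = mean(x$additive_density))
  }
  a <- one(stratum_a); b <- one(stratum_b)
  c(het_ratio = a[["het"]] / b[["het"]],
    recessive_ratio = a[["rec"]] / b[["rec"]],
    additive_ratio = a[["add"]] / b[["add"]])
}

#' Unfolded site frequency spectrum for an effect class in a stratum
#'
#' Histogram of derived-allele counts among the group's haplotypes, for
#' sites of one effect class inside one region stratum.  Requires a constant
#' non-missing haplotype count across contributing sites (the count-bin
#' convention); segregating sites only.
#'
#' @param gm A polarized [genotype_matrix()].
#' @param effects Effect-class table (see [read_effects()]).
#' @param stratum A [region_set()] delimiting the stratum.
#' @param popmap Named character vector (`sample -> group`).
#' @param group Group label.
#' @param class Effect class (`"dSNP"`, `"sSNP"` or `"SV"`).
#' @return List of class `sfs_vector`: `counts` (per derived-allele count
#'   1..2n-1), `proportions` (normalized), `n_hap`, `n_sites`.
#' @export
sfs_by_class <- function(gm, effects, stratum, popmap, group, class) {
  cls <- site_classes(gm, effects)
  widx <- site_region_index(gm, stratum)
  smp <- group_samples(gm, popmap, group)
  sel <- !is.na(widx) & !is.na(cls) & cls == class
  d <- gm$dosage[sel, smp, drop = FALSE]
  n_hap <- 2L * rowSums(!is.na(d))
  dac <- rowSums(d, na.rm = TRUE)
  seg <- dac > 0L & dac < n_hap
  if (sum(seg) < 2L) stopf("fewer than 2 segregating %s sites in stratum", class)
  n <- unique(n_hap[seg])
  if (length(n) != 1L)
    stopf("non-missing haplotype count varies across sites; cannot bin by count")
  counts <- tabulate(dac[seg], nbins = n - 1L)
  structure(list(counts = counts, proportions = counts / sum(counts),
                 n_hap = n, n_sites = sum(seg)),
            class = "sfs_vector")
}

#' Compare two site frequency spectra by paired signed rank
#'
#' Paired Wilcoxon signed-rank test over matched frequency bins of two
#' normalized spectra.  The reported statistic is the sum of signed ranks of
#' the per-bin differences `a - b` (negative when `a` places less mass than
#' `b` across the dominant bins, i.e. detects a directional shift);
#' identically equal spectra give statistic 0 and p = 1.
#'
#' @param a,b `sfs_vector` objects (see [sfs_by_class()]) or bare numeric
#'   proportion vectors of equal length.
#' @return List: `statistic` (signed-rank sum), `p_value`, `direction`.
#' @export
compare_sfs <- function(a, b) {
  pa <- if (inherits(a, "sfs_vector")) a$proportions else as.numeric(a)
  pb <- if (inherits(b, "sfs_vector")) b$proportions else as.numeric(b)
  if (length(pa) != length(pb)) stopf("spectra have different bin counts")
  d <- pa - pb
  nz <- d != 0
  if (!any(nz)) {
    return(list(statistic = 0, p_value = 1, direction = 0))
  }
  r <- rank(abs(d[nz]))
  w <- sum(sign(d[nz]) * r)
  p <- suppressWarnings(stats::wilcox.test(pa, pb, paired = TRUE)$p.value)
  list(statistic = w, p_value = p, direction = sign(w))
}

#' Frequency spectrum of introgressed candidate alleles in the recipient
#'
#' A derived allele inside an introgressed region is called an introgressed
#' candidate when its frequency is at least `donor_min` in the donor group
#' and at most `ref_max` in every reference group (populations that predate
#' the contact).  For each candidate the recipient derived-allele frequency,
#' the fraction of recipient individuals carrying at least one copy, and the
#' share of carriers that are heterozygous are reported, together with binned
#' proportions under both the allele-frequency and the carrier-fraction
#' binning.
#'
#' @param gm A polarized [genotype_matrix()].
#' @param popmap Named character vector (`sample -> group`).
#' @param donor_group Donor group label.
#' @param reference_groups Character vector of reference group labels.
#' @param recipient_group Recipient group label.
#' @param regions A [region_set()] of introgressed region calls.
#' @param donor_min,ref_max Frequency thresholds of the operational
#'   definition (defaults 0.2 and 0).
#' @param bin_edges Frequency bin edges for the summary histogram.
#' @return List: `alleles` (per-candidate table), `bins` (per-bin proportions
#'   of alleles under both binnings and mean heterozygous share), `summary`
#'   (share of candidates carried by > 50% of individuals; share with allele
#'   frequency > 50%).
#' @export
introgressed_allele_spectrum <- function(gm, popmap, donor_group,
                                         reference_groups, recipient_group,
                                         regions, donor_min = 0.2,
                                         ref_max = 0,
                                         bin_edges = seq(0, 1, by = 0.1)) {
  widx <- site_region_index(gm, regions)
  inside <- !is.na(widx)
  pd <- allele_freq(gm, group_samples(gm, popmap, donor_group))$p
  ref_ok <- rep(TRUE, n_sites(gm))
  for (rg in reference_groups) {
    pr <- allele_freq(gm, group_samples(gm, popmap, rg))$p
    ref_ok <- ref_ok & !is.na(pr) & pr <= ref_max
  }
  cand <- inside & !is.na(pd) & pd >= donor_min & ref_ok
  if (!any(cand)) {
    warning("no introgressed candidate alleles under the thresholds")
    return(list(alleles = data.frame(), bins = data.frame(), summary = list()))
  }
  rec <- gm$dosage[cand, group_samples(gm, popmap, recipient_group),
                   drop = FALSE]
  n_ind <- rowSums(!is.na(rec))
  freq <- rowSums(rec, na.rm = TRUE) / (2L * n_ind)
  carriers <- rowSums(rec >= 1L, na.rm = TRUE)
  het <- rowSums(rec == 1L, na.rm = TRUE)
  carrier_fraction <- carriers / n_ind
  het_share <- ifelse(carriers > 0L, het / carriers, NaN)
  alleles <- data.frame(chrom = gm$chrom[cand], pos = gm$pos[cand],
                        donor_freq = pd[cand], recipient_freq = freq,
                        carrier_fraction = carrier_fraction,
                        het_share = het_share)
  bin_of <- function(x) cut(x, bin_edges, include.lowest = TRUE, right = TRUE)
  bf <- bin_of(freq); bc <- bin_of(carrier_fraction)
  bins <- data.frame(bin = levels(bf),
                     prop_allele_freq = as.numeric(table(bf)) / length(freq),
                     prop_carrier_freq = as.numeric(table(bc)) / length(freq))
  hs <- tapply(het_share, bc, mean, na.rm = TRUE)
  bins$mean_het_share <- as.numeric(hs[bins$bin])
  list(alleles = alleles, bins = bins,
       summary = list(n_candidates = nrow(alleles),
                      share_carried_by_majority = mean(carrier_fraction > 0.5),
                      share_freq_above_half = mean(freq > 0.5)))
}
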