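## Genotype data model: biallelic SNP sites x diploid samples.
##
## Coordinates: `pos` is 1-based (VCF convention).  All region/window math in
## the package is 0-based half-open (BED convention); the two meet via
## `site_in_region()` which treats a site at pos p as occupying base p-1.

#' Construct a genotype matrix
#'
#' The central container of the package: biallelic SNP sites by diploid
#' samples, with dosage counting copies of the coded allele (ALT on input,
#' derived after [polarize_by_outgroup()]).
#'
#' @param chrom Character vector of contig ids, one per site.
#' @param pos Integer vector of 1-based positions, strictly increasing within
#'   each contig.
#' @param ref,alt Single-nucleotide allele strings per site.
#' @param dosage Integer matrix (sites x samples) with values 0, 1, 2 or `NA`
#'   for missing genotypes.
#' @param samples Character vector of sample ids (column names of `dosage`).
#' @param coded `"alt"` (dosage counts ALT copies) or `"derived"`.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, ref, alt, dosage, samples = colnames(dosage),
                            coded = c("alt", "derived")) {
  coded <- match.arg(coded)
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n <- length(pos)
  if (length(chrom) != n || length(ref) != n || length(alt) != n ||
      nrow(dosage) != n) {
    stopf("site annotation lengths and dosage rows disagree")
  }
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(dosage)))
  colnames(dosage) <- samples
  gm <- structure(
    list(chrom = as.character(chrom), pos = as.integer(pos),
         ref = as.character(ref), alt = as.character(alt),
         dosage = dosage, samples = samples, coded = coded),
    class = "genotype_matrix")
  validate_genotype_matrix(gm)
  gm
}

validate_genotype_matrix <- function(gm) {
  d <- gm$dosage
  bad <- d[!is.na(d)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stopf("dosage values must be in {0,1,2,NA}")
  for (ct in unique(gm$chrom)) {
    p <- gm$pos[gm$chrom == ct]
    if (length(p) > 1L && any(diff(p) <= 0L))
      stopf("positions not strictly increasing on contig %s", ct)
  }
  invisible(gm)
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d sites x %d samples (%d contig%s), coded = %s\n",
              n_sites(x), length(x$samples), length(unique(x$chrom)),
              if (length(unique(x$chrom)) == 1L) "" else "s", x$coded))
  invisible(x)
}

#' Number of sites in a genotype matrix
#' @param gm A [genotype_matrix()].
#' @return Integer site count.
#' @export
n_sites <- function(gm) length(gm$pos)

#' Subset a genotype matrix
#'
#' @param gm A [genotype_matrix()].
#' @param sites Logical or integer index over sites.
#' @param samples Character vector of sample ids (or index) to keep.
#' @return A new `genotype_matrix`.
#' @export
gm_subset <- function(gm, sites = NULL, samples = NULL) {
  if (!is.null(sites)) {
    gm$chrom <- gm$chrom[sites]; gm$pos <- gm$pos[sites]
    gm$ref <- gm$ref[sites]; gm$alt <- gm$alt[sites]
    gm$dosage <- gm$dosage[sites, , drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) {
      missing <- setdiff(samples, gm$samples)
      if (length(missing))
        stopf("samples not in matrix: %s", paste(missing, collapse = ", "))
    }
    gm$dosage <- gm$dosage[, samples, drop = FALSE]
    gm$samples <- colnames(gm$dosage)
  }
  validate_genotype_matrix(gm)
  gm
}

#' Read biallelic SNPs from a VCF into a genotype matrix
#'
#' Only biallelic SNP records (single-nucleotide REF and ALT) are retained.
#' Dosage counts ALT copies from the GT field; missing genotypes become `NA`.
#'
#' @param path Path to a VCF file (plain or bgzipped).
#' @param keep_samples Optional character vector restricting the sample set.
#' @return A [genotype_matrix()] with `coded = "alt"`.
#' @export
read_vcf <- function(path, keep_samples = NULL) {
  if (!file.exists(path)) stopf("VCF not found: %s", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") &
    !grepl(",", alt, fixed = TRUE)
  if (!any(snp)) {
    warning("no biallelic SNPs in ", path)
    smp <- colnames(v@gt)[-1]
    if (!is.null(keep_samples)) smp <- intersect(smp, keep_samples)
    return(genotype_matrix(character(), integer(), character(), character(),
                           matrix(integer(), 0, length(smp),
                                  dimnames = list(NULL, smp))))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1, dimnames = list(NULL, names(gt)))
  gt <- gt[snp, , drop = FALSE]
  if (!is.null(keep_samples)) {
    missing <- setdiff(keep_samples, colnames(gt))
    if (length(missing))
      stopf("samples not in VCF: %s", paste(missing, collapse = ", "))
    gt <- gt[, keep_samples, drop = FALSE]
  }
  dos <- gt_to_dosage(gt)
  genotype_matrix(chrom = fix[snp, "CHROM"],
                  pos = as.integer(fix[snp, "POS"]),
                  ref = ref[snp], alt = alt[snp],
                  dosage = dos, samples = colnames(gt), coded = "alt")
}

# "0/1", "1|0", "./." etc. -> ALT-copy counts; anything unparseable is NA.
gt_to_dosage <- function(gt) {
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  d <- suppressWarnings(as.integer(a1) + as.integer(a2))
  d[!is.na(d) & d > 2L] <- NA_integer_
  matrix(d, nrow = nrow(gt), dimnames = dimnames(gt))
}

#' Write a genotype matrix as a plain-text VCF
#'
#' Deterministic, minimal VCF 4.2 output (GT only) with contig header lines,
#' suitable for byte-stable round trips.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param contig_lengths Optional named vector of contig lengths for the
#'   header.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path, contig_lengths = NULL) {
  hdr <- c("##fileformat=VCFv4.2",
           "##source=clonintro",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">')
  if (!is.null(contig_lengths)) {
    hdr <- c(hdr, sprintf("##contig=<ID=%s,length=%d>",
                          names(contig_lengths), as.integer(contig_lengths)))
  }
  hdr <- c(hdr, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                        "FILTER", "INFO", "FORMAT", gm$samples),
                      collapse = "\t"))
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  d <- gm$dosage
  gt <- matrix("./.", nrow = nrow(d), ncol = ncol(d))
  ok <- !is.na(d)
  gt[ok] <- gt_code[as.character(d[ok])]
  body <- if (n_sites(gm)) {
    paste(gm$chrom, gm$pos, ".", gm$ref, gm$alt, ".", "PASS", ".", "GT",
          apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  } else character()
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Polarize a genotype matrix by outgroup consensus
#'
#' Sites where all non-missing outgroup genotypes are homozygous for one
#' allele are recoded so that dosage counts the non-outgroup (derived) allele;
#' sites with a polymorphic or entirely missing outgroup are dropped, because
#' ABBA-BABA statistics and the unfolded site frequency spectrum require
#' unambiguous derived-allele polarity.
#'
#' @param gm A [genotype_matrix()].
#' @param outgroup_samples Character vector of outgroup sample ids.
#' @return A polarized `genotype_matrix` (`coded = "derived"`) that no longer
#'   contains the dropped sites.  Outgroup columns are retained.
#' @export
polarize_by_outgroup <- function(gm, outgroup_samples) {
  if (length(outgroup_samples) == 0L) stopf("empty outgroup")
  missing <- setdiff(outgroup_samples, gm$samples)
  if (length(missing))
    stopf("outgroup samples not in matrix: %s", paste(missing, collapse = ", "))
  og <- gm$dosage[, outgroup_samples, drop = FALSE]
  n_nm <- rowSums(!is.na(og))
  all0 <- rowSums(og == 0L, na.rm = TRUE) == n_nm & n_nm > 0L
  all2 <- rowSums(og == 2L, na.rm = TRUE) == n_nm & n_nm > 0L
  keep <- all0 | all2
  gm <- gm_subset(gm, sites = keep)
  flip <- all2[keep]
  if (any(flip)) {
    gm$dosage[flip, ] <- 2L - gm$dosage[flip, , drop = FALSE]
    tmp <- gm$ref[flip]
    gm$ref[flip] <- gm$alt[flip]
    gm$alt[flip] <- tmp
  }
  gm$coded <- "derived"
  gm
}

#' Read a population map
#'
#' Two-column TSV (sample id, group label), no header.
#'
#' @param path Path to the TSV.
#' @return Named character vector: `popmap[sample] = group`.
#' @export
read_popmap <- function(path) {
  tb <- utils::read.table(path, header = FALSE, sep = "\t",
                          col.names = c("sample", "group"),
                          colClasses = "character")
  stats::setNames(tb$group, tb$sample)
}

#' Write a population map
#' @param popmap Named character vector (`sample -> group`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(popmap, path) {
  utils::write.table(data.frame(sample = names(popmap), group = unname(popmap)),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Per-site derived/ALT allele frequency and non-missing haplotype count for a
# set of samples.  Frequency is NaN where every call is missing.
allele_freq <- function(gm, samples) {
  d <- gm$dosage[, samples, drop = FALSE]
  n_hap <- 2L * rowSums(!is.na(d))
  p <- rowSums(d, na.rm = TRUE) / n_hap
  list(p = p, n_hap = n_hap)
}

# Samples belonging to a group, validated against the matrix.
group_samples <- function(gm, popmap, group) {
  smp <- names(popmap)[popmap == group]
  smp <- intersect(smp, gm$samples)
  if (length(smp) == 0L) stopf("group '%s' has no samples in the matrix", group)
  smp
}
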