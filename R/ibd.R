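## Method-of-moments IBD estimation (PLINK --genome semantics).
##
## For each sample pair, counts of identity-by-state (IBS) 0/1/2 sites are
## compared with their expectations given cohort allele frequencies to solve
## for P(IBD = 0/1/2).  Because frequencies are estimated from a finite
## cohort, raw monomials such as p^2 q^2 are biased; each is replaced by its
## unbiased estimator under sampling without replacement from the X observed
## alleles (hypergeometric factorial moments), e.g.
##   est(p^2 q^2) = p(p - 1/X) q(q - 1/X) * X^3 / ((X-1)(X-2)(X-3)).

# Corrected per-site expected IBS-state probabilities conditional on IBD
# state, for frequency vector p and allele count X.  Returns a list of
# vectors e00, e10, e20, e11, e21 (e22 = 1 identically).
ibs_expectations <- function(p, X) {
  q <- 1 - p
  a1 <- X / (X - 1); a2 <- X / (X - 2); a3 <- X / (X - 3)
  c2 <- a1            # two distinct draws
  c3 <- a1 * a2       # three
  c4 <- a1 * a2 * a3  # four
  x <- 1 / X
  p2q2 <- p * (p - x) * q * (q - x) * c4
  p3q  <- p * (p - x) * (p - 2 * x) * q * c4
  pq3  <- q * (q - x) * (q - 2 * x) * p * c4
  p4   <- p * (p - x) * (p - 2 * x) * (p - 3 * x) * c4
  q4   <- q * (q - x) * (q - 2 * x) * (q - 3 * x) * c4
  p2q  <- p * (p - x) * q * c3
  pq2  <- q * (q - x) * p * c3
  p3   <- p * (p - x) * (p - 2 * x) * c3
  q3   <- q * (q - x) * (q - 2 * x) * c3
  list(e00 = 2 * p2q2,
       e10 = 4 * p3q + 4 * pq3,
       e20 = p4 + q4 + 4 * p2q2,
       e11 = 2 * p2q + 2 * pq2,
       e21 = p3 + q3 + p2q + pq2)
}

#' Pairwise relatedness (PI_HAT) by method of moments
#'
#' Estimates the IBD sharing proportion between sample pairs from IBS state
#' counts and cohort allele frequencies, following the PLINK `--genome`
#' method of moments with small-sample bias corrections.  Negative
#' intermediate IBD-state probabilities are clamped to zero and the triple is
#' renormalized; `pi_hat = P(IBD=1)/2 + P(IBD=2)`, clamped to `[0, 1]`.
#'
#' @param gm A [genotype_matrix()]; allele frequencies are estimated from all
#'   of its samples.
#' @param pairs Optional two-column matrix/data.frame of sample ids; default
#'   is every unordered pair.
#' @param min_informative Pairs with fewer informative sites (polymorphic,
#'   frequency estimable from >= 4 alleles, both genotypes present) are
#'   flagged `low_confidence`.
#' @return Data.frame: `id1`, `id2`, `z0`, `z1`, `z2`, `pi_hat`,
#'   `n_informative`, `low_confidence`.
#' @export
pairwise_pi_hat <- function(gm, pairs = NULL, min_informative = 50) {
  if (is.null(pairs)) {
    cmb <- utils::combn(gm$samples, 2)
    pairs <- data.frame(id1 = cmb[1, ], id2 = cmb[2, ])
  } else {
    pairs <- data.frame(id1 = as.character(pairs[[1]]),
                        id2 = as.character(pairs[[2]]))
  }
  fr <- allele_freq(gm, gm$samples)
  informative <- is.finite(fr$p) & fr$p > 0 & fr$p < 1 & fr$n_hap >= 4L
  p <- fr$p[informative]
  X <- fr$n_hap[informative]
  ee <- ibs_expectations(p, X)
  d <- gm$dosage[informative, , drop = FALSE]

  res <- lapply(seq_len(nrow(pairs)), function(i) {
    d1 <- d[, pairs$id1[i]]
    d2 <- d[, pairs$id2[i]]
    ok <- !is.na(d1) & !is.na(d2)
    ibs <- 2L - abs(d1[ok] - d2[ok])
    n_sites_pair <- sum(ok)
    N0 <- sum(ibs == 0L); N1 <- sum(ibs == 1L); N2 <- sum(ibs == 2L)
    E00 <- sum(ee$e00[ok]); E10 <- sum(ee$e10[ok]); E20 <- sum(ee$e20[ok])
    E11 <- sum(ee$e11[ok]); E21 <- sum(ee$e21[ok]); E22 <- n_sites_pair
    z0 <- if (E00 > 0) N0 / E00 else 0
    z1 <- if (E11 > 0) (N1 - z0 * E10) / E11 else 0
    z2 <- if (E22 > 0) (N2 - z0 * E20 - z1 * E21) / E22 else 0
    z <- pmax(c(z0, z1, z2), 0)
    if (sum(z) > 0) z <- z / sum(z) else z <- c(1, 0, 0)
    pi_hat <- min(max(z[2] / 2 + z[3], 0), 1)
    data.frame(id1 = pairs$id1[i], id2 = pairs$id2[i],
               z0 = z[1], z1 = z[2], z2 = z[3], pi_hat = pi_hat,
               n_informative = n_sites_pair,
               low_confidence = n_sites_pair < min_informative)
  })
  do.call(rbind, res)
}
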