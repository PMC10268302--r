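## ABBA-BABA family statistics for an ordered trio (P1, P2, P3) plus
## outgroup O, computed from population derived-allele frequencies.
##
## Direction convention: positive D/fd/fdM means excess sharing between P2
## and the candidate donor P3 (e.g. donor -> recipient when the recipient is
## placed as P2).

#' Per-site derived-allele frequencies for an ordered trio plus outgroup
#'
#' @param gm A polarized [genotype_matrix()] (`coded = "derived"`, see
#'   [polarize_by_outgroup()]).
#' @param popmap Named character vector (`sample -> group`).
#' @param trio Named character vector with elements `P1`, `P2`, `P3`, `O`
#'   giving the group label bound to each role.
#' @return Data.frame: `chrom`, `pos`, `p1`..`p4`.  Sites where any role has
#'   zero non-missing calls are excluded.
#' @export
trio_site_freqs <- function(gm, popmap, trio) {
  roles <- c("P1", "P2", "P3", "O")
  if (!all(roles %in% names(trio)))
    stopf("trio must name roles P1, P2, P3 and O")
  if (gm$coded != "derived")
    stopf("genotype matrix must be polarized (coded = 'derived')")
  fr <- lapply(roles, function(r)
    allele_freq(gm, group_samples(gm, popmap, trio[[r]])))
  keep <- Reduce(`&`, lapply(fr, function(f) f$n_hap > 0L))
  data.frame(chrom = gm$chrom[keep], pos = gm$pos[keep],
             p1 = fr[[1]]$p[keep], p2 = fr[[2]]$p[keep],
             p3 = fr[[3]]$p[keep], p4 = fr[[4]]$p[keep])
}

# Per-site ABBA/BABA sums and the fd / fdM denominators.
site_patterns <- function(fq) {
  p1 <- fq$p1; p2 <- fq$p2; p3 <- fq$p3; p4 <- fq$p4
  abba <- (1 - p1) * p2 * p3 * (1 - p4)
  baba <- p1 * (1 - p2) * p3 * (1 - p4)
  pd <- pmax(p2, p3)
  den_fd <- (1 - p1) * pd * pd * (1 - p4) - p1 * (1 - pd) * pd * (1 - p4)
  pd1 <- pmax(p1, p3)
  den_alt <- -((1 - pd1) * p2 * pd1 * (1 - p4) - pd1 * (1 - p2) * pd1 * (1 - p4))
  den_fdm <- ifelse(p2 >= p1, den_fd, den_alt)
  list(abba = abba, baba = baba, den_fd = den_fd, den_fdm = den_fdm)
}

#' Windowed D, fd and fdM
#'
#' Per site, `ABBA = (1-p1) p2 p3 (1-p4)` and `BABA = p1 (1-p2) p3 (1-p4)`;
#' per window, `D = sum(ABBA-BABA) / sum(ABBA+BABA)`.  The admixture-fraction
#' estimator fd replaces both P2 and P3 in the denominator by the higher of
#' the two frequencies (the inferred donor) and is reported `NaN` for windows
#' with a non-positive numerator sum, where it is undefined.  fdM uses the
#' same numerator but a denominator that switches to P1/P3 sharing (with
#' negated sign) at sites where `p1 > p2`, making it symmetric about zero.
#'
#' @param freqs Site frequencies from [trio_site_freqs()].
#' @param windows Windows from [make_windows()].
#' @return Data.frame per window: coordinates, `n_sites_used`, `sum_abba`,
#'   `sum_baba`, `D`, `fd`, `fdM`, `valid`.
#' @export
window_abba_baba <- function(freqs, windows) {
  sp <- site_patterns(freqs)
  gm_like <- list(chrom = freqs$chrom, pos = freqs$pos)
  widx <- site_region_index(gm_like, windows)
  n_used <- integer(nrow(windows))
  tb <- table(widx[!is.na(widx)])
  n_used[as.integer(names(tb))] <- as.integer(tb)
  s_abba <- window_sum(sp$abba, widx, windows)
  s_baba <- window_sum(sp$baba, widx, windows)
  s_dfd <- window_sum(sp$den_fd, widx, windows)
  s_dfdm <- window_sum(sp$den_fdm, widx, windows)
  num <- s_abba - s_baba
  D <- num / (s_abba + s_baba)
  D[is.finite(s_abba + s_baba) & (s_abba + s_baba) == 0] <- NaN
  fd <- num / s_dfd
  fd[!is.na(num) & num <= 0] <- NaN
  fd[is.finite(s_dfd) & s_dfd == 0] <- NaN
  fdm <- num / s_dfdm
  fdm[is.finite(s_dfdm) & s_dfdm == 0] <- NaN
  data.frame(chrom = windows$chrom, start = windows$start, end = windows$end,
             n_sites_used = n_used, sum_abba = s_abba, sum_baba = s_baba,
             D = D, fd = fd, fdM = fdm, valid = windows$valid)
}

#' Block-jackknife standard error for genome-wide D
#'
#' Delete-one-window jackknife over valid windows of a [window_abba_baba()]
#' result.
#'
#' @param trio_result Output of [window_abba_baba()].
#' @return List with `D` (genome-wide), `se`, `z` and `n_blocks`.
#' @export
d_jackknife <- function(trio_result) {
  ok <- trio_result$valid & is.finite(trio_result$sum_abba) &
    is.finite(trio_result$sum_baba) & trio_result$n_sites_used > 0
  a <- trio_result$sum_abba[ok]
  b <- trio_result$sum_baba[ok]
  n <- length(a)
  if (n < 2L) stopf("need at least two valid windows for the jackknife")
  D_all <- (sum(a) - sum(b)) / (sum(a) + sum(b))
  D_del <- ((sum(a) - a) - (sum(b) - b)) / ((sum(a) - a) + (sum(b) - b))
  pseudo <- n * D_all - (n - 1) * D_del
  se <- sqrt(stats::var(pseudo) / n)
  list(D = D_all, se = se, z = D_all / se, n_blocks = n)
}

#' Genome-wide f4-admixture ratio for one trio
#'
#' The standard admixture-fraction estimator on outgroup-polarized
#' frequencies: `f(A,B,C) = sum[p3 (p2 - p1)] / sum[p3 (p3 - p1)]` with
#' `P1 = A`, `P2 = B`, `P3 = C` (the donor standing in for itself in the
#' denominator).
#'
#' @inheritParams trio_site_freqs
#' @param a,b,c_donor Group labels for P1, P2 and the donor P3.
#' @param outgroup Outgroup group label.
#' @return A single f estimate.
#' @export
f4_ratio <- function(gm, popmap, a, b, c_donor, outgroup) {
  fq <- trio_site_freqs(gm, popmap,
                        c(P1 = a, P2 = b, P3 = c_donor, O = outgroup))
  num <- sum(fq$p3 * (fq$p2 - fq$p1) * (1 - fq$p4))
  den <- sum(fq$p3 * (fq$p3 - fq$p1) * (1 - fq$p4))
  if (den == 0) return(NaN)
  num / den
}

#' f-branch matrix over a rooted population tree
#'
#' Assigns f4-ratio admixture signals to specific branches: for a branch `b`
#' and candidate donor `C`,
#' `fb(b, C) = median over A of [ min over B in descendants(b) of f(A,B,C) ]`
#' where `A` ranges over the tips of the sister clade of `b` and `C` over
#' tips branching off above the parent of `b` (trios inconsistent with the
#' tree, including donors that descend from `b`, give `NaN`).  Negative
#' values are floored at zero.
#'
#' @inheritParams trio_site_freqs
#' @param tree A rooted tree (`ape::phylo` or newick string) whose tips are
#'   ingroup group labels; an outgroup tip is dropped if present.
#' @param outgroup Outgroup group label (also the polarization reference).
#' @return List with `fb` (matrix branch x donor), `tree` (the pruned
#'   `phylo`), and `branches` (descendant tips per branch).
#' @export
fbranch <- function(gm, popmap, tree, outgroup) {
  if (is.character(tree)) tree <- ape::read.tree(text = tree)
  if (outgroup %in% tree$tip.label)
    tree <- ape::drop.tip(tree, outgroup)
  tips <- tree$tip.label
  known <- unique(popmap)
  if (!all(tips %in% known))
    stopf("tree tips missing from popmap: %s",
          paste(setdiff(tips, known), collapse = ", "))
  ntip <- length(tips)
  root <- ntip + 1L

  desc_tips <- function(node) {
    if (node <= ntip) return(tips[node])
    tips[intersect(unlist(phangorn_free_descendants(tree, node)), seq_len(ntip))]
  }

  # Branches = every edge's child node except the root.
  nodes <- tree$edge[, 2]
  f_cache <- new.env(parent = emptyenv())
  f_memo <- function(a, b, cc) {
    key <- paste(a, b, cc, sep = "\r")
    if (!is.null(f_cache[[key]])) return(f_cache[[key]])
    val <- f4_ratio(gm, popmap, a, b, cc, outgroup)
    f_cache[[key]] <- val
    val
  }

  fb <- matrix(NaN, nrow = length(nodes), ncol = ntip,
               dimnames = list(NULL, tips))
  branch_names <- character(length(nodes))
  for (i in seq_along(nodes)) {
    node <- nodes[i]
    below <- desc_tips(node)
    branch_names[i] <- paste(sort(below), collapse = ",")
    parent <- tree$edge[tree$edge[, 2] == node, 1]
    siblings <- setdiff(tree$edge[tree$edge[, 1] == parent, 2], node)
    a_tips <- unlist(lapply(siblings, desc_tips))
    above <- setdiff(tips, c(below, a_tips))
    for (cc in above) {
      vals <- vapply(a_tips, function(a)
        min(vapply(below, function(b) f_memo(a, b, cc), numeric(1))),
        numeric(1))
      fb[i, cc] <- max(stats::median(vals), 0)
    }
  }
  rownames(fb) <- branch_names
  list(fb = fb, tree = tree, branches = branch_names)
}

# Tips/nodes below `node` (inclusive) without depending on phangorn: simple
# stack descent over the edge matrix.
phangorn_free_descendants <- function(tree, node) {
  out <- integer()
  stack <- node
  while (length(stack)) {
    cur <- stack[[1]]
    stack <- stack[-1]
    out <- c(out, cur)
    stack <- c(stack, tree$edge[tree$edge[, 1] == cur, 2])
  }
  out
}

#' Top-quantile fd regions
#'
#' Valid windows whose fd is at or above the `(1-q)` quantile of valid-window
#' fd values; all tied windows at the threshold are included.
#'
#' @param trio_result Output of [window_abba_baba()].
#' @param q Upper-tail fraction in (0, 1), e.g. `0.05` for the top 5%.
#' @return A [region_set()] labelled `top_fd` with the window fd as `score`.
#' @export
top_quantile_regions <- function(trio_result, q = 0.05) {
  if (q <= 0 || q >= 1) stopf("q must be in (0, 1)")
  ok <- trio_result$valid & is.finite(trio_result$fd)
  if (!any(ok)) stopf("no valid windows with finite fd")
  thr <- stats::quantile(trio_result$fd[ok], probs = 1 - q, names = FALSE)
  sel <- ok & trio_result$fd >= thr
  rs <- region_set(trio_result$chrom[sel], trio_result$start[sel],
                   trio_result$end[sel], label = "top_fd")
  ord <- order(trio_result$chrom[sel], trio_result$start[sel])
  rs$score <- trio_result$fd[sel][ord]
  rs
}

#' Mean gene count per fd bin
#'
#' Windows are assigned to fd bins; the gene count of a window is the number
#' of gene intervals overlapping it by at least 1 bp (a gene straddling two
#' windows counts once in each).
#'
#' @param trio_result Output of [window_abba_baba()].
#' @param genes A [region_set()] of gene intervals (same 0-based half-open
#'   coordinates).
#' @param bin_edges Numeric fd bin edges (left-closed, right-open; the last
#'   bin is closed).
#' @return Data.frame per bin: `bin`, `n_windows`, `mean_genes` (`NaN` for
#'   empty bins).
#' @export
genes_per_fd_bin <- function(trio_result, genes, bin_edges) {
  ok <- trio_result$valid & is.finite(trio_result$fd)
  wr <- region_set(trio_result$chrom[ok], trio_result$start[ok],
                   trio_result$end[ok], label = "window")
  ord <- order(trio_result$chrom[ok], trio_result$start[ok])
  fd <- trio_result$fd[ok][ord]
  counts <- integer(nrow(wr))
  for (ct in unique(wr$chrom)) {
    wi <- which(wr$chrom == ct)
    gi <- genes[genes$chrom == ct, ]
    if (!nrow(gi)) next
    hits <- IRanges::findOverlaps(IRanges::IRanges(wr$start[wi] + 1, wr$end[wi]),
                                  IRanges::IRanges(gi$start + 1, gi$end))
    tb <- table(S4Vectors::queryHits(hits))
    counts[wi[as.integer(names(tb))]] <- as.integer(tb)
  }
  bins <- cut(fd, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  out <- data.frame(bin = levels(bins),
                    n_windows = as.integer(table(bins)))
  means <- tapply(counts, bins, mean)
  out$mean_genes <- as.numeric(means[out$bin])
  out$mean_genes[out$n_windows == 0L] <- NaN
  out
}
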