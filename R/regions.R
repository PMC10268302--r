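## Region algebra.  All regions are 0-based half-open [start, end) as in BED.
## A RegionSet is a data.frame with columns chrom, start, end, label plus any
## extra annotation columns (score, n_snps, valid, ...).

#' Construct a region set
#'
#' @param chrom,start,end Region coordinates, 0-based half-open.
#' @param label Region label (recycled).
#' @param ... Further annotation columns (recycled by `data.frame`).
#' @return A `region_set` data.frame sorted by (chrom, start, end).
#' @export
region_set <- function(chrom = character(), start = integer(), end = integer(),
                       label = "region", ...) {
  n <- max(length(chrom), length(start), length(end))
  label <- if (n) rep_len(as.character(label), n) else character()
  rs <- data.frame(chrom = if (n) rep_len(as.character(chrom), n) else character(),
                   start = as.numeric(start), end = as.numeric(end),
                   label = label, ..., stringsAsFactors = FALSE)
  if (nrow(rs) && any(rs$start >= rs$end)) stopf("regions must satisfy start < end")
  if (nrow(rs) && any(rs$start < 0)) stopf("negative region start")
  rs <- rs[order(rs$chrom, rs$start, rs$end), , drop = FALSE]
  rownames(rs) <- NULL
  class(rs) <- c("region_set", "data.frame")
  rs
}

#' Coerce a data.frame with region columns to a region set
#'
#' @param df Data.frame with `chrom`, `start`, `end`, `label` (extra columns
#'   are carried along).
#' @return A [region_set()].
#' @export
as_region_set <- function(df) {
  do.call(region_set, c(as.list(df[c("chrom", "start", "end", "label")]),
                        as.list(df[setdiff(names(df),
                                           c("chrom", "start", "end", "label"))])))
}

# Per-chromosome IRanges view (1-based closed) of a region set.
rs_iranges <- function(rs) {
  lapply(split(rs, rs$chrom), function(x)
    IRanges::IRanges(start = x$start + 1, end = x$end))
}

#' Read a BED file as a region set
#'
#' Columns beyond the first three are read as `label` (4th) and `score`
#' (5th) when present.
#'
#' @param path Path to a BED (plain TSV) file.
#' @return A [region_set()].
#' @export
read_bed <- function(path) {
  tb <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  names(tb)[1:3] <- c("chrom", "start", "end")
  label <- if (ncol(tb) >= 4) tb[[4]] else "region"
  rs <- region_set(tb$chrom, tb$start, tb$end, label = label)
  if (ncol(tb) >= 5) rs$score <- tb[[5]][order(tb$chrom, tb$start, tb$end)]
  rs
}

#' Write a region set as BED
#'
#' Emits chrom, start, end, label and, when present, score — producing output
#' that [read_bed()] round-trips exactly.
#'
#' @param rs A [region_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(rs, path) {
  cols <- rs[, intersect(c("chrom", "start", "end", "label", "score"), names(rs))]
  cols$start <- format(cols$start, scientific = FALSE, trim = TRUE)
  cols$end <- format(cols$end, scientific = FALSE, trim = TRUE)
  utils::write.table(cols, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Tile contigs into non-overlapping windows
#'
#' Produces `[k*size, (k+1)*size)` tiles per contig; a trailing partial tile is
#' kept and flagged, so that genome-wide fractions computed over windows are
#' well defined.  Each window is annotated with its biallelic SNP count from
#' `gm` and a validity flag `n_snps >= min_snps` (windowed statistics are only
#' trustworthy with enough segregating sites; scans in this package require
#' 100 SNPs per window by default).
#'
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param size Window size in bp.
#' @param min_snps Minimum SNP count for a window to be `valid`.
#' @param gm Optional [genotype_matrix()] used to count SNPs per window.
#' @return A [region_set()] with columns `n_snps`, `valid`, `partial`.
#' @export
make_windows <- function(contig_lengths, size, min_snps = 100, gm = NULL) {
  if (size <= 0) stopf("window size must be positive")
  if (!is.null(gm)) {
    absent <- setdiff(unique(gm$chrom), names(contig_lengths))
    if (length(absent))
      stopf("contigs in genotype matrix missing from contig_lengths: %s",
            paste(absent, collapse = ", "))
  }
  pieces <- lapply(names(contig_lengths), function(ct) {
    len <- contig_lengths[[ct]]
    starts <- seq(0, len - 1, by = size)
    ends <- pmin(starts + size, len)
    data.frame(chrom = ct, start = starts, end = ends,
               partial = ends - starts < size)
  })
  w <- do.call(rbind, pieces)
  rs <- region_set(w$chrom, w$start, w$end, label = "window", partial = w$partial)
  rs$n_snps <- if (is.null(gm)) 0L else count_sites_in_regions(gm, rs)
  rs$valid <- rs$n_snps >= min_snps
  rs
}

#' Count genotype-matrix sites per region
#'
#' A site at 1-based position `p` occupies 0-based coordinate `p - 1`.
#'
#' @param gm A [genotype_matrix()].
#' @param rs A [region_set()].
#' @return Integer vector, one count per region.
#' @export
count_sites_in_regions <- function(gm, rs) {
  n <- integer(nrow(rs))
  for (ct in unique(rs$chrom)) {
    ridx <- which(rs$chrom == ct)
    p0 <- gm$pos[gm$chrom == ct] - 1L
    if (!length(p0)) next
    n[ridx] <- vapply(ridx, function(i)
      sum(p0 >= rs$start[i] & p0 < rs$end[i]), integer(1))
  }
  n
}

# Window index (row of rs) per site; NA where a site is in no window.
# Assumes rs windows are disjoint within chrom.
site_region_index <- function(gm, rs) {
  idx <- rep(NA_integer_, n_sites(gm))
  for (ct in unique(gm$chrom)) {
    sidx <- which(gm$chrom == ct)
    ridx <- which(rs$chrom == ct)
    if (!length(ridx)) next
    p0 <- gm$pos[sidx] - 1L
    ord <- order(rs$start[ridx])
    ridx <- ridx[ord]
    k <- findInterval(p0, rs$start[ridx])
    inside <- k >= 1L & p0 < rs$end[ridx[pmax(k, 1L)]]
    idx[sidx[inside]] <- ridx[k[inside]]
  }
  idx
}

#' Merge nearby regions
#'
#' Same-chromosome regions separated by a gap smaller than `max_gap` bp (or
#' overlapping, regardless of gap) are unioned.
#'
#' @param rs A [region_set()] (single label).
#' @param max_gap Merge gap threshold in bp; `0` merges only overlaps.
#' @return A merged [region_set()].
#' @export
merge_regions <- function(rs, max_gap = 0) {
  if (max_gap < 0) stopf("max_gap must be non-negative")
  if (nrow(rs) == 0L) return(rs)
  out <- lapply(split(rs, rs$chrom), function(x) {
    ir <- IRanges::reduce(IRanges::IRanges(x$start + 1, x$end),
                          min.gapwidth = max_gap)
    data.frame(chrom = x$chrom[1], start = IRanges::start(ir) - 1,
               end = IRanges::end(ir), label = x$label[1])
  })
  out <- do.call(rbind, out)
  region_set(out$chrom, out$start, out$end, label = out$label)
}

#' Summarise overlap between two region sets
#'
#' @param a,b [region_set()]s in the same coordinate convention.
#' @return List with `n_overlapping` (a-regions touching >= 1 b-region by
#'   >= 1 bp), `shared_bp` (total intersection length), and
#'   `fraction_a_overlapped` (shared bp / total bp of `a`).
#' @export
region_overlap_summary <- function(a, b) {
  n_overlap <- 0L
  shared <- 0
  for (ct in unique(a$chrom)) {
    ai <- a[a$chrom == ct, ]
    bi <- b[b$chrom == ct, ]
    if (!nrow(bi)) next
    ira <- IRanges::IRanges(ai$start + 1, ai$end)
    irb <- IRanges::IRanges(bi$start + 1, bi$end)
    hits <- IRanges::findOverlaps(ira, irb)
    n_overlap <- n_overlap + length(unique(S4Vectors::queryHits(hits)))
    if (length(hits)) {
      ov <- IRanges::pintersect(ira[S4Vectors::queryHits(hits)],
                                irb[S4Vectors::subjectHits(hits)])
      shared <- shared + sum(IRanges::width(ov))
    }
  }
  total_a <- sum(a$end - a$start)
  list(n_overlapping = n_overlap, shared_bp = shared,
       fraction_a_overlapped = if (total_a > 0) shared / total_a else NaN)
}

# Per a-region overlapped bp by (the union of) b.
region_coverage_bp <- function(a, b) {
  cov <- numeric(nrow(a))
  bu <- merge_regions(region_set(b$chrom, b$start, b$end), max_gap = 0)
  for (ct in unique(a$chrom)) {
    ai <- which(a$chrom == ct)
    bi <- bu[bu$chrom == ct, ]
    if (!nrow(bi)) next
    ira <- IRanges::IRanges(a$start[ai] + 1, a$end[ai])
    irb <- IRanges::IRanges(bi$start + 1, bi$end)
    hits <- IRanges::findOverlaps(ira, irb)
    if (length(hits)) {
      w <- IRanges::width(IRanges::pintersect(ira[S4Vectors::queryHits(hits)],
                                              irb[S4Vectors::subjectHits(hits)]))
      per_a <- tapply(w, S4Vectors::queryHits(hits), sum)
      cov[ai[as.integer(names(per_a))]] <- as.numeric(per_a)
    }
  }
  cov
}

#' Random length-matched control regions
#'
#' For each replicate, places one random region per template region with the
#' identical length, uniformly over valid starts on a random contig
#' (probability proportional to the number of valid start positions), with
#' rejection sampling so controls within a replicate do not overlap each
#' other.  Used as the negative control for load-density contrasts.
#'
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param template A [region_set()] whose region lengths are reproduced.
#' @param n_reps Number of control replicates.
#' @param seed Integer seed; identical seeds give identical placements.
#' @param max_tries Rejection-sampling retries per region before aborting.
#' @return List of `n_reps` [region_set()]s labelled `control_<i>`.
#' @export
random_control_regions <- function(contig_lengths, template, n_reps = 100,
                                   seed = 1, max_tries = 1000) {
  lens <- template$end - template$start
  if (any(lens > max(contig_lengths)))
    stopf("template region longer than every contig")
  lens <- sort(lens, decreasing = TRUE)  # longest-first eases packing
  with_seed(seed, {
    lapply(seq_len(n_reps), function(rep_i) {
      placed <- list()
      for (j in seq_along(lens)) {
        ok <- FALSE
        for (try in seq_len(max_tries)) {
          wts <- pmax(contig_lengths - lens[j] + 1, 0)
          ct <- sample(names(contig_lengths), 1, prob = wts / sum(wts))
          start <- floor(stats::runif(1, 0, contig_lengths[[ct]] - lens[j] + 1))
          end <- start + lens[j]
          clash <- any(vapply(placed, function(r)
            r$chrom == ct && start < r$end && r$start < end, logical(1)))
          if (!clash) {
            placed[[j]] <- list(chrom = ct, start = start, end = end)
            ok <- TRUE
            break
          }
        }
        if (!ok) stopf("could not place control region of %d bp without overlap",
                       lens[j])
      }
      region_set(vapply(placed, `[[`, "", "chrom"),
                 vapply(placed, `[[`, 0, "start"),
                 vapply(placed, `[[`, 0, "end"),
                 label = sprintf("control_%d", rep_i))
    })
  })
}

#' Complement of a region set within contigs
#'
#' @param rs A [region_set()].
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param label Label for the complement regions.
#' @return A [region_set()] covering every base not in `rs`.
#' @export
complement_regions <- function(rs, contig_lengths, label = "complement") {
  u <- merge_regions(region_set(rs$chrom, rs$start, rs$end), max_gap = 0)
  out <- list()
  for (ct in names(contig_lengths)) {
    len <- contig_lengths[[ct]]
    ui <- u[u$chrom == ct, ]
    bounds <- c(0, rbind(ui$start, ui$end), len)
    starts <- bounds[seq(1, length(bounds), by = 2)]
    ends <- bounds[seq(2, length(bounds), by = 2)]
    keep <- starts < ends
    if (any(keep))
      out[[ct]] <- data.frame(chrom = ct, start = starts[keep], end = ends[keep])
  }
  if (!length(out)) return(region_set(label = label))
  out <- do.call(rbind, out)
  region_set(out$chrom, out$start, out$end, label = label)
}
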