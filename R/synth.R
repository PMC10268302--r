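## Synthetic five-population dataset with known introgressed ancestry
## tracts: two Middle-East-like wild groups, a diverged low-diversity
## EU-like wild donor, and two cultivated analogs (table, wine) with a
## recent clonal history and a donor pulse that is several-fold stronger
## into the wine analog.  Every pipeline stage can be validated against the
## emitted truth tracts.

#' Scenario configuration for the synthetic dataset
#'
#' The split schedule is: ancestor -> (EU-like donor with reduced N,
#' ME lineage); ME lineage -> (ME1, ME2 lineage); ME2 lineage -> (ME2,
#' cultivated ancestor); cultivated -> (table, wine).  After the final
#' split, a hybridization pulse from the EU-like donor hits the wine analog
#' at `m_wine` and the table analog at `m_table` (default ratio 5:1,
#' mirroring the asymmetric gene flow the scenario emulates), followed by a
#' few outcrossing (backcross) generations and a clonal phase.
#'
#' @param contig_lengths Named vector of contig lengths (bp).
#' @param n_sites Polymorphic site slots across the genome.
#' @param N_anc,N_eu,N_me,N_cult Diploid sizes per branch (`N_eu` is
#'   deliberately the smallest, giving the donor reduced diversity).
#' @param t_burn,t1,t2,t3,t4_pre,t4_backcross,t4_clonal Branch durations in
#'   generations (ancestor burn-in; EU/ME to ME1/ME2 split; to cultivated
#'   split; to table/wine split; pre-pulse; post-pulse outcrossing; clonal).
#' @param m_wine,m_table Pulse hybrid fractions into the two cultivated
#'   analogs.
#' @param mu,r Per-bp mutation and recombination rates.
#' @param n_sample Named vector: emitted samples per group.
#' @param n_outgroup Outgroup samples (emitted as fixed-ancestral).
#' @param effect_probs Named probabilities for assigning `dSNP`, `sSNP` and
#'   `SV` effect classes to emitted sites.
#' @param seed Root seed.
#' @return A validated `scenario_config` list.
#' @export
scenario_config <- function(contig_lengths = c(chr1 = 1e6),
                            n_sites = 3000,
                            N_anc = 100, N_eu = 30, N_me = 80, N_cult = 70,
                            t_burn = 30, t1 = 40, t2 = 15, t3 = 10,
                            t4_pre = 5, t4_backcross = 8, t4_clonal = 8,
                            m_wine = 0.15, m_table = 0.03,
                            mu = 3e-8, r = 3e-6,
                            n_sample = c(ME1 = 8, ME2 = 8, EU = 8,
                                         table = 10, wine = 10),
                            n_outgroup = 4,
                            effect_probs = c(dSNP = 0.15, sSNP = 0.3,
                                             SV = 0.05),
                            seed = 1) {
  cfg <- as.list(environment())
  if (any(c(t_burn, t1, t2, t3) <= 0) || any(c(t4_pre, t4_backcross,
                                               t4_clonal) < 0))
    stopf("degenerate schedule: branch durations must be positive")
  if (m_wine < 0 || m_wine >= 1 || m_table < 0 || m_table >= 1)
    stopf("pulse fractions must be in [0, 1)")
  if (sum(effect_probs) > 1) stopf("effect probabilities exceed 1")
  if (length(contig_lengths) != 1L)
    stopf("the scenario currently uses a single contig")
  class(cfg) <- "scenario_config"
  cfg
}

# Found a daughter population of size N from st.
split_population <- function(st, N) {
  founders <- sample.int(nrow(st$H1), N, replace = N > nrow(st$H1))
  st$H1 <- st$H1[founders, , drop = FALSE]
  st$H2 <- st$H2[founders, , drop = FALSE]
  st$O1 <- st$O1[founders, , drop = FALSE]
  st$O2 <- st$O2[founders, , drop = FALSE]
  st
}

evolve <- function(st, gens, mode, engine_cfg) {
  for (g in seq_len(gens)) st <- sim_generation(st, mode, engine_cfg)
  st
}

#' Generate the synthetic five-population dataset
#'
#' Runs the forward engine over the split schedule, emits a VCF (derived
#' allele as ALT, outgroup samples homozygous ancestral), a population map,
#' donor-ancestry truth tracts per cultivated sample, and an effect-class
#' table.  Fully seed-reproducible: the same config yields byte-identical
#' files.
#'
#' @param cfg A [scenario_config()].
#' @param out_dir Optional directory; when given, writes `data.vcf`,
#'   `popmap.tsv`, `truth.bed`, `effects.tsv` and `config.yaml`.
#' @return List: `gm` (ALT-coded [genotype_matrix()] including outgroup
#'   samples), `popmap`, `truth` (tract [region_set()], label = sample id),
#'   `effects`, `contig_lengths`, `config`, `paths` (when written).
#' @export
generate_dataset <- function(cfg, out_dir = NULL) {
  stopifnot(inherits(cfg, "scenario_config"))
  L <- unname(cfg$contig_lengths[[1]])
  contig <- names(cfg$contig_lengths)[1]
  engine <- list(L = L, r = cfg$r, mu = cfg$mu, h = 0.5, h_deleterious = NULL)

  res <- with_seed(cfg$seed, {
    pos <- sort(ceiling(stats::runif(cfg$n_sites, 0, L)))
    pos <- unique(pos)
    S <- length(pos)
    s0 <- numeric(S)
    cls0 <- rep("neutral", S)
    # ancestral standing variation from the neutral SFS (P(count = i) ~ 1/i)
    two_n <- 2L * cfg$N_anc
    cnt <- sample.int(two_n - 1L, S, replace = TRUE,
                      prob = 1 / seq_len(two_n - 1L))
    anc <- new_sim_state(cfg$N_anc, S, pos, s0, cls0, init_freq = cnt / two_n)
    anc <- evolve(anc, cfg$t_burn, "outcrossing", engine)

    eu <- split_population(anc, cfg$N_eu)
    me <- split_population(anc, cfg$N_me)
    eu <- evolve(eu, cfg$t1, "outcrossing", engine)
    me <- evolve(me, cfg$t1, "outcrossing", engine)

    me1 <- split_population(me, cfg$N_me)
    me2line <- split_population(me, cfg$N_me)
    eu <- evolve(eu, cfg$t2, "outcrossing", engine)
    me1 <- evolve(me1, cfg$t2, "outcrossing", engine)
    me2line <- evolve(me2line, cfg$t2, "outcrossing", engine)

    me2 <- split_population(me2line, cfg$N_me)
    cult <- split_population(me2line, cfg$N_cult)
    eu <- evolve(eu, cfg$t3, "outcrossing", engine)
    me1 <- evolve(me1, cfg$t3, "outcrossing", engine)
    me2 <- evolve(me2, cfg$t3, "outcrossing", engine)
    cult <- evolve(cult, cfg$t3, "outcrossing", engine)

    tab <- split_population(cult, cfg$N_cult)
    wine <- split_population(cult, cfg$N_cult)
    wild_tick <- function(gens) {
      eu <<- evolve(eu, gens, "outcrossing", engine)
      me1 <<- evolve(me1, gens, "outcrossing", engine)
      me2 <<- evolve(me2, gens, "outcrossing", engine)
    }
    wild_tick(cfg$t4_pre)
    tab <- evolve(tab, cfg$t4_pre, "outcrossing", engine)
    wine <- evolve(wine, cfg$t4_pre, "outcrossing", engine)

    if (cfg$m_wine > 0) wine <- hybridize(wine, eu, cfg$m_wine, engine)
    if (cfg$m_table > 0) tab <- hybridize(tab, eu, cfg$m_table, engine)

    wild_tick(cfg$t4_backcross)
    tab <- evolve(tab, cfg$t4_backcross, "outcrossing", engine)
    wine <- evolve(wine, cfg$t4_backcross, "outcrossing", engine)
    wild_tick(cfg$t4_clonal)
    tab <- evolve(tab, cfg$t4_clonal, "clonal", engine)
    wine <- evolve(wine, cfg$t4_clonal, "clonal", engine)

    pops <- list(ME1 = me1, ME2 = me2, EU = eu, table = tab, wine = wine)
    emit_dataset(pops, cfg, pos, contig, L)
  })

  res$contig_lengths <- cfg$contig_lengths
  res$config <- cfg
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- list(vcf = file.path(out_dir, "data.vcf"),
                  popmap = file.path(out_dir, "popmap.tsv"),
                  truth = file.path(out_dir, "truth.bed"),
                  effects = file.path(out_dir, "effects.tsv"),
                  config = file.path(out_dir, "config.yaml"))
    write_vcf(res$gm, paths$vcf, contig_lengths = cfg$contig_lengths)
    write_popmap(res$popmap, paths$popmap)
    write_bed(res$truth, paths$truth)
    write_effects(res$effects, paths$effects)
    cfg_plain <- unclass(cfg)
    cfg_plain$contig_lengths <- as.list(cfg$contig_lengths)
    cfg_plain$n_sample <- as.list(cfg$n_sample)
    cfg_plain$effect_probs <- as.list(cfg$effect_probs)
    yaml::write_yaml(cfg_plain, paths$config)
    res$paths <- paths
  }
  res
}

# Sample individuals, build the genotype matrix, truth tracts and effect
# classes.  Runs inside the scenario RNG stream.
emit_dataset <- function(pops, cfg, pos, contig, L) {
  sampled <- list()
  popmap <- character()
  for (g in names(cfg$n_sample)) {
    idx <- sample.int(nrow(pops[[g]]$H1), cfg$n_sample[[g]])
    ids <- sprintf("%s_%02d", g, seq_along(idx))
    sampled[[g]] <- list(idx = idx, ids = ids, st = pops[[g]])
    popmap[ids] <- g
  }
  og_ids <- sprintf("OUT_%02d", seq_len(cfg$n_outgroup))
  popmap[og_ids] <- "OUT"

  dos <- list()
  for (g in names(sampled)) {
    st <- sampled[[g]]$st
    idx <- sampled[[g]]$idx
    d <- t((st$H1[idx, , drop = FALSE] != 0L) +
             (st$H2[idx, , drop = FALSE] != 0L))
    colnames(d) <- sampled[[g]]$ids
    dos[[g]] <- d
  }
  dos[["OUT"]] <- matrix(0L, length(pos), cfg$n_outgroup,
                         dimnames = list(NULL, og_ids))
  dosage <- do.call(cbind, dos)

  keep <- rowSums(dosage) > 0L  # polymorphic among emitted samples
  pos_keep <- pos[keep]
  n_keep <- sum(keep)
  alleles <- matrix(replicate(n_keep, sample(c("A", "C", "G", "T"), 2)),
                    nrow = 2)
  gm <- genotype_matrix(chrom = rep(contig, n_keep), pos = pos_keep,
                        ref = alleles[1, ], alt = alleles[2, ],
                        dosage = dosage[keep, , drop = FALSE], coded = "alt")

  truth <- truth_tracts(sampled[c("table", "wine")], keep, pos_keep, contig, L)

  u <- stats::runif(n_keep)
  pd <- cfg$effect_probs[["dSNP"]]; ps <- cfg$effect_probs[["sSNP"]]
  pv <- cfg$effect_probs[["SV"]]
  cls <- rep(NA_character_, n_keep)
  cls[u < pd] <- "dSNP"
  cls[u >= pd & u < pd + ps] <- "sSNP"
  cls[u >= pd + ps & u < pd + ps + pv] <- "SV"
  effects <- data.frame(chrom = contig, pos = pos_keep,
                        class = cls)[!is.na(cls), ]
  rownames(effects) <- NULL

  list(gm = gm, popmap = popmap, truth = truth, effects = effects)
}

# Donor-ancestry tracts per sampled cultivated individual: maximal runs of
# flagged emitted sites per haplotype, with boundaries midway to the
# flanking native site (tract edges between markers are unobservable, so a
# midpoint convention is fixed); union over the two haplotypes per sample.
truth_tracts <- function(sampled_cult, keep, pos_keep, contig, L) {
  c0 <- pos_keep - 1L  # 0-based site coordinates
  runs_to_regions <- function(flags) {
    r <- rle(flags)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    on <- which(r$values)
    if (!length(on)) return(NULL)
    lo <- starts[on]; hi <- ends[on]
    prev <- c0[pmax(lo - 1L, 1L)]
    nxt <- c0[pmin(hi + 1L, length(flags))]
    b_start <- floor((prev + c0[lo]) / 2) + 1
    b_start[lo == 1L] <- 0
    b_end <- floor((c0[hi] + nxt) / 2) + 1
    b_end[hi == length(flags)] <- L
    data.frame(start = b_start, end = b_end)
  }
  out <- list()
  for (g in names(sampled_cult)) {
    st <- sampled_cult[[g]]$st
    idx <- sampled_cult[[g]]$idx
    ids <- sampled_cult[[g]]$ids
    for (j in seq_along(idx)) {
      segs <- rbind(runs_to_regions(st$O1[idx[j], keep]),
                    runs_to_regions(st$O2[idx[j], keep]))
      if (is.null(segs) || !nrow(segs)) next
      rs <- merge_regions(region_set(contig, segs$start, segs$end,
                                     label = ids[j]), max_gap = 0)
      rs$label <- ids[j]
      out[[ids[j]]] <- rs
    }
  }
  if (!length(out))
    return(region_set(label = "truth"))
  as_region_set(do.call(rbind, out))
}

#' Spike heterozygous deleterious load into truth tracts
#'
#' Reassigns `dSNP`/`sSNP` labels (SV labels are untouched) so that the
#' heterozygous-dSNP density of the recipient group inside the truth-tract
#' union is `enrichment` times the outside density, by repeated random
#' assignment keeping the draw whose realized enrichment is closest to the
#' target.  The realized value is recorded so parameter-recovery checks have
#' an exact reference.
#'
#' @param dataset Output of [generate_dataset()].
#' @param enrichment Target fold enrichment (>= 0).
#' @param seed Seed for the assignment.
#' @param recipient_group Group whose heterozygote counts define density
#'   (default `"wine"`).
#' @param n_dsnp Total dSNP budget; default keeps the dataset's current
#'   dSNP count.
#' @param max_tries Random assignments attempted.
#' @return The dataset with updated `effects` and entries
#'   `realized_enrichment`, `target_enrichment`.
#' @export
spike_load <- function(dataset, enrichment, seed = 1,
                       recipient_group = "wine", n_dsnp = NULL,
                       max_tries = 50) {
  truth <- dataset$truth
  if (!nrow(truth)) stopf("dataset has no truth tracts to spike")
  gm <- dataset$gm
  tract_u <- merge_regions(region_set(truth$chrom, truth$start, truth$end),
                           max_gap = 0)
  bp_in <- sum(tract_u$end - tract_u$start)
  bp_out <- sum(dataset$contig_lengths) - bp_in
  rec <- group_samples(gm, dataset$popmap, recipient_group)
  het_cnt <- rowSums(gm$dosage[, rec, drop = FALSE] == 1L, na.rm = TRUE)
  sv <- site_classes(gm, dataset$effects) == "SV"
  sv[is.na(sv)] <- FALSE
  inside <- !is.na(site_region_index(gm, tract_u))
  cand_in <- which(inside & !sv & het_cnt > 0)
  cand_out <- which(!inside & !sv & het_cnt > 0)
  if (is.null(n_dsnp)) n_dsnp <- sum(dataset$effects$class == "dSNP")
  if (n_dsnp == 0L) stopf("zero dSNP budget: nothing to assign")

  hbar_in <- mean(het_cnt[cand_in])
  hbar_out <- mean(het_cnt[cand_out])
  A <- hbar_in / bp_in
  B <- hbar_out / bp_out
  n_in <- round(n_dsnp * (enrichment * B) / (A + enrichment * B))
  n_out <- n_dsnp - n_in
  if (n_in > length(cand_in))
    stopf(paste0("tracts too small to realize enrichment: need %d in-tract ",
                 "heterozygous sites, have %d"), n_in, length(cand_in))
  if (n_out > length(cand_out))
    stopf("background too small: need %d sites, have %d", n_out,
          length(cand_out))

  realized <- function(sel_in, sel_out) {
    (sum(het_cnt[sel_in]) / bp_in) / (sum(het_cnt[sel_out]) / bp_out)
  }
  pick <- with_seed(seed, {
    best <- NULL
    for (i in seq_len(max_tries)) {
      si <- sample(cand_in, n_in)
      so <- sample(cand_out, n_out)
      r <- realized(si, so)
      if (is.null(best) || abs(r - enrichment) < abs(best$r - enrichment))
        best <- list(si = si, so = so, r = r)
    }
    best
  })

  dsnp_sites <- c(pick$si, pick$so)
  cls <- rep(NA_character_, n_sites(gm))
  cls[sv] <- "SV"
  cls[dsnp_sites] <- "dSNP"
  # keep the original sSNP budget on the remaining sites, deterministically
  n_ssnp <- sum(dataset$effects$class == "sSNP")
  free <- which(is.na(cls))
  ssnp_sites <- with_seed(seed + 1L, sample(free, min(n_ssnp, length(free))))
  cls[ssnp_sites] <- "sSNP"
  eff <- data.frame(chrom = gm$chrom, pos = gm$pos, class = cls)
  dataset$effects <- eff[!is.na(eff$class), ]
  rownames(dataset$effects) <- NULL
  dataset$realized_enrichment <- pick$r
  dataset$target_enrichment <- enrichment
  dataset
}

#' fd contrast between truth tracts and the genomic background
#'
#' Weighted comparison of window fd over introgressed truth tracts versus
#' the rest of the genome: each valid window's fd is weighted by the
#' fraction of (window x recipient-sample) space covered by truth tracts
#' for the tract mean, and by its complement for the background mean.  The
#' coverage weighting keeps the contrast defined even when every window
#' touches some sample's tract.
#'
#' @param trio_result Output of [window_abba_baba()].
#' @param truth Truth-tract [region_set()] (label = sample id).
#' @param n_recipient_samples Number of recipient samples the tracts refer
#'   to.
#' @return List: `fd_tract`, `fd_background`, `difference`.
#' @export
fd_tract_contrast <- function(trio_result, truth, n_recipient_samples) {
  ok <- trio_result$valid & is.finite(trio_result$fd)
  if (!any(ok)) stopf("no valid windows with finite fd")
  win <- region_set(trio_result$chrom[ok], trio_result$start[ok],
                    trio_result$end[ok])
  ord <- order(trio_result$chrom[ok], trio_result$start[ok])
  fd <- trio_result$fd[ok][ord]
  cov <- numeric(nrow(win))
  for (id in unique(truth$label)) {
    cov <- cov + region_coverage_bp(win, truth[truth$label == id, ])
  }
  cov <- cov / ((win$end - win$start) * n_recipient_samples)
  cov <- pmin(cov, 1)
  w_t <- cov; w_b <- 1 - cov
  list(fd_tract = sum(fd * w_t) / sum(w_t),
       fd_background = sum(fd * w_b) / sum(w_b),
       difference = sum(fd * w_t) / sum(w_t) - sum(fd * w_b) / sum(w_b))
}
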