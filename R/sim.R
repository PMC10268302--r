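## Diploid Wright-Fisher forward simulator with outcrossing and clonal
## propagation, hybridization pulses, and per-copy introgressed-origin
## tracking.
##
## State layout: two N x S integer matrices of allele ids (0 = ancestral,
## any non-zero id = derived; mutations create fresh ids, i.e. the
## infinite-alleles convention per site, so per-site heterozygosity has the
## closed-form neutral equilibrium theta/(1+theta) with theta = 4N mu').
## Origin flags are two parallel logical matrices marking copies inherited
## from a donor gamete; a new mutation on a flagged background clears the
## flag (origin changes only by reproduction, never by relabeling).

#' Forward-simulation configuration
#'
#' @param N_recipient,N_donor Diploid population sizes.
#' @param L Genome length in bp.
#' @param n_sites Number of tracked polymorphic site slots, placed uniformly
#'   on `[1, L]`.
#' @param mu Per-bp per-gamete mutation rate (expected new mutations per
#'   gamete = `mu * L`; clonal individuals mutate at the same per-haplotype
#'   rate, i.e. `2 mu L` per individual per generation).
#' @param r Per-bp recombination rate (expected crossovers per gamete =
#'   `r * L`).
#' @param dfe Distribution of fitness effects for derived alleles:
#'   `p_beneficial` (probability a selected site is beneficial),
#'   `s_beneficial_mean` (exponential mean), `s_deleterious_mean` and
#'   `s_deleterious_shape` (gamma, applied with negative sign).  Zero means
#'   give neutral alleles.
#' @param h Dominance coefficient; `h_deleterious` optionally overrides it
#'   for deleterious alleles (e.g. 0 for fully recessive).
#' @param n_donor_sites Number of donor-fixed differential sites carried by
#'   the default donor population at the pulse.
#' @param hybrid_fraction Proportion of the recipient population replaced by
#'   F1 individuals at the pulse (0 disables the pulse).
#' @param burnin_generations Outcrossing generations before the pulse.
#' @param schedule Post-pulse propagation schedule: list of stages, each
#'   `list(mode = "outcrossing"|"clonal", generations = n)`.
#' @param init_freq Optional length-`n_sites` vector of initial derived
#'   frequencies for recipient standing variation (linkage equilibrium);
#'   default all ancestral.
#' @param record_every Record the trajectory every this many generations.
#' @param snapshot_generations Post-pulse generations at which to snapshot
#'   the SFS and DFE of surviving introgressed alleles.
#' @param replicates Number of replicates.
#' @param seed Root seed; per-replicate streams are derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(N_recipient = 500, N_donor = 100, L = 1e6,
                       n_sites = 2000, mu = 5e-8, r = 5e-7,
                       dfe = list(p_beneficial = 0.5,
                                  s_beneficial_mean = 0.05,
                                  s_deleterious_mean = 0.05,
                                  s_deleterious_shape = 0.5),
                       h = 0.5, h_deleterious = NULL,
                       n_donor_sites = 100, hybrid_fraction = 0.1,
                       burnin_generations = 0,
                       schedule = list(list(mode = "outcrossing", generations = 10),
                                       list(mode = "clonal", generations = 2000)),
                       init_freq = NULL, record_every = 10,
                       snapshot_generations = integer(), replicates = 1,
                       seed = 1) {
  cfg <- list(N_recipient = N_recipient, N_donor = N_donor, L = L,
              n_sites = n_sites, mu = mu, r = r, dfe = dfe, h = h,
              h_deleterious = h_deleterious, n_donor_sites = n_donor_sites,
              hybrid_fraction = hybrid_fraction,
              burnin_generations = burnin_generations, schedule = schedule,
              init_freq = init_freq, record_every = record_every,
              snapshot_generations = snapshot_generations,
              replicates = replicates, seed = seed)
  if (any(c(N_recipient, L, n_sites) <= 0)) stopf("sizes must be positive")
  if (mu < 0 || r < 0) stopf("rates must be non-negative")
  if (hybrid_fraction < 0 || hybrid_fraction > 1)
    stopf("hybrid_fraction must be in [0, 1]")
  total <- sum(vapply(schedule, `[[`, 0, "generations"))
  if (length(snapshot_generations) && max(snapshot_generations) > total)
    stopf("snapshot generation beyond the schedule (%d generations)", total)
  modes <- vapply(schedule, `[[`, "", "mode")
  if (!all(modes %in% c("outcrossing", "clonal")))
    stopf("schedule modes must be 'outcrossing' or 'clonal'")
  class(cfg) <- "sim_config"
  cfg
}

# Draw selection coefficients and classes for n sites.
draw_dfe <- function(n, dfe) {
  ben <- stats::runif(n) < dfe$p_beneficial
  s <- numeric(n)
  cls <- rep("neutral", n)
  if (dfe$s_beneficial_mean > 0) {
    s[ben] <- stats::rexp(sum(ben), rate = 1 / dfe$s_beneficial_mean)
    cls[ben] <- "beneficial"
  }
  if (dfe$s_deleterious_mean > 0) {
    sh <- dfe$s_deleterious_shape
    s[!ben] <- -stats::rgamma(sum(!ben), shape = sh,
                              scale = dfe$s_deleterious_mean / sh)
    cls[!ben] <- "deleterious"
  }
  s <- pmax(s, -0.95)  # truncate the gamma tail short of lethality
  list(s = s, class = cls)
}

new_sim_state <- function(N, n_sites, pos, s, class, init_freq = NULL) {
  H <- function() matrix(0L, N, n_sites)
  O <- function() matrix(FALSE, N, n_sites)
  st <- list(H1 = H(), H2 = H(), O1 = O(), O2 = O(),
             pos = pos, s = s, class = class, mut_counter = 1L)
  if (!is.null(init_freq)) {
    st$H1[] <- as.integer(stats::runif(N * n_sites) < rep(init_freq, each = N))
    st$H2[] <- as.integer(stats::runif(N * n_sites) < rep(init_freq, each = N))
  }
  st
}

# Multiplicative fitness: w = prod (1+s)^{hom} (1+h s)^{het}.
sim_fitness <- function(st, h, h_del = NULL) {
  if (!any(st$s != 0)) return(rep(1, nrow(st$H1)))  # neutral fast path
  hvec <- rep(h, length(st$s))
  if (!is.null(h_del)) hvec[st$class == "deleterious"] <- h_del
  d1 <- st$H1 != 0L
  d2 <- st$H2 != 0L
  hom <- d1 & d2
  het <- xor(d1, d2)
  lw_hom <- log(pmax(1 + st$s, 1e-12))
  lw_het <- log(pmax(1 + hvec * st$s, 1e-12))
  as.numeric(exp(hom %*% lw_hom + het %*% lw_het))
}

# Haplotype-choice masks (values 1/2) for n gametes: crossover count
# Poisson(r L), breakpoints uniform on [0, L], random starting haplotype.
gamete_masks <- function(n, pos, L, rL) {
  S <- length(pos)
  start <- sample.int(2L, n, replace = TRUE)
  M <- matrix(rep(start, S), n, S)
  k <- stats::rpois(n, rL)
  for (i in which(k > 0L)) {
    bp <- sort(stats::runif(k[i], 0, L))
    parity <- findInterval(pos, bp) %% 2L
    M[i, parity == 1L] <- 3L - start[i]
  }
  M
}

# Form one gamete per entry of parent_idx (alleles + origin flags).
make_gametes <- function(st, parent_idx, L, rL) {
  M <- gamete_masks(length(parent_idx), st$pos, L, rL)
  A <- st$H1[parent_idx, , drop = FALSE]
  O <- st$O1[parent_idx, , drop = FALSE]
  sel2 <- M == 2L
  A[sel2] <- st$H2[parent_idx, , drop = FALSE][sel2]
  O[sel2] <- st$O2[parent_idx, , drop = FALSE][sel2]
  list(A = A, O = O)
}

# Place Poisson(rate) new mutations per row of A; fresh allele ids, native
# origin.  Returns updated (A, O, counter).
apply_mutations <- function(A, O, rate, counter) {
  n <- nrow(A)
  k <- stats::rpois(n, rate)
  tot <- sum(k)
  if (tot > 0L) {
    rows <- rep(seq_len(n), k)
    cols <- sample.int(ncol(A), tot, replace = TRUE)
    idx <- cbind(rows, cols)
    A[idx] <- counter + seq_len(tot) - 1L
    O[idx] <- FALSE
    counter <- counter + tot
  }
  list(A = A, O = O, counter = counter)
}

# One generation; mode "outcrossing" or "clonal".
sim_generation <- function(st, mode, cfg) {
  N <- nrow(st$H1)
  w <- sim_fitness(st, cfg$h, cfg$h_deleterious)
  if (all(w <= 0))
    stopf("population is nonviable (all fitness zero) — check the DFE")
  if (mode == "outcrossing") {
    if (N < 2L) stopf("outcrossing requires N >= 2")
    p1 <- sample.int(N, N, replace = TRUE, prob = w)
    p2 <- sample.int(N, N, replace = TRUE, prob = w)
    same <- p1 == p2
    while (any(same)) {  # no selfing
      p2[same] <- sample.int(N, sum(same), replace = TRUE, prob = w)
      same <- p1 == p2
    }
    g1 <- make_gametes(st, p1, cfg$L, cfg$r * cfg$L)
    g2 <- make_gametes(st, p2, cfg$L, cfg$r * cfg$L)
    m1 <- apply_mutations(g1$A, g1$O, cfg$mu * cfg$L, st$mut_counter)
    m2 <- apply_mutations(g2$A, g2$O, cfg$mu * cfg$L, m1$counter)
    st$H1 <- m1$A; st$O1 <- m1$O
    st$H2 <- m2$A; st$O2 <- m2$O
    st$mut_counter <- m2$counter
  } else {
    par <- sample.int(N, N, replace = TRUE, prob = w)
    st$H1 <- st$H1[par, , drop = FALSE]
    st$H2 <- st$H2[par, , drop = FALSE]
    st$O1 <- st$O1[par, , drop = FALSE]
    st$O2 <- st$O2[par, , drop = FALSE]
    # both haplotypes mutate: rate mu L per haplotype
    m1 <- apply_mutations(st$H1, st$O1, cfg$mu * cfg$L, st$mut_counter)
    m2 <- apply_mutations(st$H2, st$O2, cfg$mu * cfg$L, m1$counter)
    st$H1 <- m1$A; st$O1 <- m1$O
    st$H2 <- m2$A; st$O2 <- m2$O
    st$mut_counter <- m2$counter
  }
  st
}

#' Hybridization pulse
#'
#' Replaces `floor(hybrid_fraction * N)` randomly chosen recipient
#' individuals with F1s formed from one donor gamete and one recipient
#' gamete (both with recombination).  Every position inherited from the
#' donor gamete is flagged introgressed, so F1s are heterozygous — and
#' flagged — at all donor-fixed differential sites.
#'
#' @param st Recipient simulation state.
#' @param donor Donor simulation state (same site panel).
#' @param hybrid_fraction Fraction of recipients replaced.
#' @param cfg A [sim_config()] (provides `L` and `r`).
#' @return Updated recipient state.
#' @export
hybridize <- function(st, donor, hybrid_fraction, cfg) {
  if (hybrid_fraction > 1) stopf("hybrid_fraction must be <= 1")
  N <- nrow(st$H1)
  n_f1 <- floor(hybrid_fraction * N)
  if (n_f1 == 0L) return(st)
  who <- sample.int(N, n_f1)
  donor_par <- sample.int(nrow(donor$H1), n_f1, replace = TRUE)
  rec_par <- sample.int(N, n_f1, replace = TRUE)
  gd <- make_gametes(donor, donor_par, cfg$L, cfg$r * cfg$L)
  gr <- make_gametes(st, rec_par, cfg$L, cfg$r * cfg$L)
  st$H1[who, ] <- gd$A
  st$O1[who, ] <- TRUE          # donor ancestry, every position
  st$H2[who, ] <- gr$A
  st$O2[who, ] <- gr$O
  st
}

# Default donor population: fixed derived (and pre-flagged ancestry is
# irrelevant — hybridize() flags the donor gamete) at n_donor_sites randomly
# chosen sites whose s comes from the DFE.
make_default_donor <- function(cfg, pos, s, class) {
  donor_sites <- sort(sample.int(cfg$n_sites, min(cfg$n_donor_sites, cfg$n_sites)))
  st <- new_sim_state(cfg$N_donor, cfg$n_sites, pos, s, class)
  st$H1[, donor_sites] <- 1L
  st$H2[, donor_sites] <- 1L
  attr(st, "donor_sites") <- donor_sites
  st
}

# Per-site introgressed-copy counts.
introgressed_copy_counts <- function(st) {
  colSums((st$H1 != 0L) & st$O1) + colSums((st$H2 != 0L) & st$O2)
}

sim_record <- function(st, generation) {
  cnt <- introgressed_copy_counts(st)
  two_n <- 2L * nrow(st$H1)
  seg <- cnt > 0L & cnt < two_n
  data.frame(
    generation = generation,
    total_introgressed_copies = sum(cnt),
    surviving_introgressed_sites = sum(cnt > 0L),
    seg_introgressed_sites = sum(seg),
    seg_introgressed_beneficial = sum(seg & st$class == "beneficial"),
    seg_introgressed_deleterious = sum(seg & st$class == "deleterious"),
    fixed_introgressed_sites = sum(cnt == two_n),
    mean_heterozygosity = mean(st$H1 != st$H2))
}

sim_snapshot <- function(st, generation) {
  cnt <- introgressed_copy_counts(st)
  alive <- cnt > 0L
  list(generation = generation,
       freq = cnt[alive] / (2 * nrow(st$H1)),
       s = st$s[alive], class = st$class[alive])
}

#' Run the forward simulator
#'
#' Per generation: (1) fitness `w = prod (1+s)^hom (1+hs)^het`; (2)
#' reproduction — outcrossing samples two distinct parents proportional to
#' `w` and forms recombinant gametes, clonal propagation samples one parent
#' proportional to `w` and copies the diploid genotype exactly; (3) mutation
#' at rate `mu L` per gamete (per haplotype for clones).  An optional
#' hybridization pulse precedes the schedule.  Fully seeded: replicate `i`
#' uses a stream derived deterministically from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @param keep_state Return the final state of each replicate (for e.g. VCF
#'   export).
#' @return List of replicates, each `list(trajectory = data.frame,
#'   snapshots = list, final_state = state or NULL, donor_sites)`.
#' @export
run_forward <- function(cfg, keep_state = FALSE) {
  seeds <- derive_seeds(cfg$seed, cfg$replicates)
  lapply(seq_len(cfg$replicates), function(rep_i) {
    with_seed(seeds[rep_i], run_forward_once(cfg, keep_state))
  })
}

run_forward_once <- function(cfg, keep_state = FALSE) {
  pos <- sort(stats::runif(cfg$n_sites, 1, cfg$L))
  eff <- draw_dfe(cfg$n_sites, cfg$dfe)
  st <- new_sim_state(cfg$N_recipient, cfg$n_sites, pos, eff$s, eff$class,
                      cfg$init_freq)
  for (g in seq_len(cfg$burnin_generations))
    st <- sim_generation(st, "outcrossing", cfg)
  donor_sites <- integer()
  if (cfg$hybrid_fraction > 0) {
    donor <- make_default_donor(cfg, pos, eff$s, eff$class)
    donor_sites <- attr(donor, "donor_sites")
    st <- hybridize(st, donor, cfg$hybrid_fraction, cfg)
  }
  traj <- list(sim_record(st, 0L))
  snaps <- list()
  if (0 %in% cfg$snapshot_generations) snaps[["0"]] <- sim_snapshot(st, 0L)
  g <- 0L
  for (stage in cfg$schedule) {
    for (i in seq_len(stage$generations)) {
      st <- sim_generation(st, stage$mode, cfg)
      g <- g + 1L
      if (g %% cfg$record_every == 0L)
        traj[[length(traj) + 1L]] <- sim_record(st, g)
      if (g %in% cfg$snapshot_generations)
        snaps[[as.character(g)]] <- sim_snapshot(st, g)
    }
  }
  list(trajectory = do.call(rbind, traj), snapshots = snaps,
       final_state = if (keep_state) st else NULL,
       donor_sites = donor_sites)
}

#' Heterozygosity under outcrossing versus clonal propagation
#'
#' Evolves the same starting conditions (identical per-replicate seeds)
#' under pure outcrossing and under pure clonal propagation, with mutation
#' on and no pulse, recording mean per-individual heterozygosity.
#' Outcrossing reaches the neutral mutation-drift equilibrium
#' `theta/(1+theta)` per site; clones accumulate heterozygosity without
#' bound because their haplotypes never recombine or reassort.
#'
#' @param cfg A [sim_config()]; its `schedule` supplies the duration (the
#'   modes are overridden), and `hybrid_fraction` is forced to 0.
#' @return List with elements `outcrossing` and `clonal`, each a list of
#'   replicate trajectories.
#' @export
heterozygosity_experiment <- function(cfg) {
  total <- sum(vapply(cfg$schedule, `[[`, 0, "generations"))
  run_mode <- function(mode) {
    cfg2 <- cfg
    cfg2$hybrid_fraction <- 0
    cfg2$schedule <- list(list(mode = mode, generations = total))
    class(cfg2) <- "sim_config"
    run_forward(cfg2)
  }
  list(outcrossing = run_mode("outcrossing"), clonal = run_mode("clonal"))
}

#' Introgression dynamics: clonal-transition arm versus outcrossing arm
#'
#' Runs the pulse experiment twice from identical seeds: the clonal arm uses
#' the configured schedule (canonically 10 outcrossing generations after the
#' pulse, then strict clonality), the outcrossing arm replaces every stage
#' with outcrossing for the same total duration.
#'
#' @param cfg A [sim_config()] with `hybrid_fraction > 0`.
#' @return List with `clonal` and `outcrossing` arms (replicate lists as in
#'   [run_forward()]).
#' @export
introgression_experiment <- function(cfg) {
  total <- sum(vapply(cfg$schedule, `[[`, 0, "generations"))
  out_cfg <- cfg
  out_cfg$schedule <- list(list(mode = "outcrossing", generations = total))
  class(out_cfg) <- "sim_config"
  list(clonal = run_forward(cfg), outcrossing = run_forward(out_cfg))
}

#' Canonical desk-scale configuration of the introgression pulse experiment
#'
#' The reference parameterization used throughout the package for the
#' pulse-then-clonality experiment: a diploid recipient of N = 200, a donor
#' fixed for 150 differential sites (half beneficial with exponential
#' effects, mean s = 0.03; half deleterious with gamma(shape 2) effects,
#' mean s = -0.03; h = 0.5), a pulse replacing 15% of recipients with F1s,
#' 10 outcrossing generations, then strict clonality.  New mutation is
#' negligible during the experiment so the dynamics tracked are those of the
#' pulse alleles alone (a continuing influx of beneficial mutations would
#' cause clonal interference and indefinitely delay the clonal plateau).
#' Effect sizes sit in the strong-selection desk regime (N|s| ~ 5-10): weak
#' enough per allele that the outcrossing arm approaches equilibrium slowly,
#' strong enough in clone-level aggregate that clonal takeover is decisive.
#'
#' @param replicates Number of replicates.
#' @param seed Root seed.
#' @param clonal_generations Length of the clonal phase.
#' @param snapshot_generations Passed through to [sim_config()].
#' @return A [sim_config()].
#' @export
pulse_experiment_config <- function(replicates = 20, seed = 1,
                                    clonal_generations = 990,
                                    snapshot_generations = integer()) {
  sim_config(
    N_recipient = 200, N_donor = 100, L = 1e6, n_sites = 150,
    mu = 1e-9, r = 5e-7,
    dfe = list(p_beneficial = 0.5, s_beneficial_mean = 0.03,
               s_deleterious_mean = 0.03, s_deleterious_shape = 2),
    h = 0.5, n_donor_sites = 150, hybrid_fraction = 0.15,
    burnin_generations = 0,
    schedule = list(list(mode = "outcrossing", generations = 10),
                    list(mode = "clonal", generations = clonal_generations)),
    record_every = 10, snapshot_generations = snapshot_generations,
    replicates = replicates, seed = seed)
}

#' Detect the plateau of a trajectory
#'
#' Operational equilibrium rule: the first recorded generation from which
#' the 50-generation sliding mean of the series changes by less than `tol`
#' (relative) — and keeps doing so for the remainder of the run.  Requiring
#' the change to stay small distinguishes the true equilibrium from the
#' transient trough where early purging of deleterious copies balances the
#' rise of beneficial ones.
#'
#' @param trajectory A replicate trajectory (data.frame with `generation`).
#' @param column Column to examine.
#' @param window Sliding-window width in generations.
#' @param tol Relative change threshold.
#' @return The plateau generation, or `NA` if the series is still changing
#'   at the end of the run.
#' @export
detect_plateau <- function(trajectory, column = "total_introgressed_copies",
                           window = 50, tol = 0.01) {
  g <- trajectory$generation
  v <- trajectory[[column]]
  changing <- vapply(seq_along(g), function(i) {
    if (g[i] < 2 * window) return(NA)
    recent <- v[g > g[i] - window & g <= g[i]]
    previous <- v[g > g[i] - 2 * window & g <= g[i] - window]
    if (!length(recent) || !length(previous)) return(NA)
    m1 <- mean(previous); m2 <- mean(recent)
    if (m1 == 0 && m2 == 0) return(FALSE)  # absorbed at zero
    !(m1 > 0 && abs(m2 - m1) / m1 < tol)
  }, logical(1))
  idx <- which(!is.na(changing))
  if (!length(idx)) return(NA_real_)
  active <- idx[changing[idx]]
  if (!length(active)) return(g[idx[1]])
  last_active <- max(active)
  later <- idx[g[idx] > g[last_active]]
  if (!length(later)) return(NA_real_)
  g[min(later)]
}

#' Modal frequency of surviving introgressed alleles
#'
#' Pools surviving introgressed allele frequencies (optionally across
#' replicates) and reports the centre of the modal 10%-wide frequency bin,
#' in percent.  Bins are centred on multiples of 10% so that the
#' heterozygous-clone signature (all frequencies at exactly 1/2) lands in
#' the 50% bin.
#'
#' @param freqs Numeric vector of allele frequencies in `[0, 1]`.
#' @param bin_width Bin width on the frequency scale (default 0.1).
#' @return Modal bin centre in percent.
#' @export
modal_frequency_percent <- function(freqs, bin_width = 0.1) {
  centers <- seq(0, 1, by = bin_width)
  idx <- round(freqs / bin_width) + 1
  idx <- pmin(pmax(idx, 1), length(centers))
  tb <- tabulate(idx, nbins = length(centers))
  100 * centers[which.max(tb)]
}
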