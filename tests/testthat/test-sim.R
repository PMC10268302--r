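neutral_dfe <- list(p_beneficial = 0, s_beneficial_mean = 0,
                    s_deleterious_mean = 0, s_deleterious_shape = 1)

small_cfg <- function(...) {
  args <- list(N_recipient = 30, L = 1e5, n_sites = 50, mu = 0, r = 1e-6,
               dfe = neutral_dfe, n_donor_sites = 20, hybrid_fraction = 0,
               schedule = list(list(mode = "outcrossing", generations = 20)),
               record_every = 5, replicates = 1, seed = 2)
  dots <- list(...)
  args[names(dots)] <- dots   # wholesale replacement (modifyList would
                              # silently skip unnamed schedule entries)
  do.call(sim_config, args)
}

test_that("no pulse means no introgressed copies, ever", {
  res <- run_forward(small_cfg(hybrid_fraction = 0, mu = 1e-8))
  expect_true(all(res[[1]]$trajectory$total_introgressed_copies == 0))
})

test_that("clonal propagation without mutation copies genotypes exactly", {
  cfg <- small_cfg(N_recipient = 1, mu = 0,
                   schedule = list(list(mode = "clonal", generations = 30)),
                   init_freq = rep(0.5, 50))
  res <- run_forward(cfg, keep_state = TRUE)
  tr <- res[[1]]$trajectory
  expect_equal(length(unique(tr$mean_heterozygosity)), 1L)

  # with N > 1: every offspring genotype equals some parent genotype bitwise.
  # Re-running the same seed with zero generations recovers the parent pool.
  key <- function(st) paste(apply(st$H1, 1, paste, collapse = ","),
                            apply(st$H2, 1, paste, collapse = ","))
  for (s in 1:3) {
    cfg1 <- small_cfg(N_recipient = 10, mu = 0, init_freq = rep(0.3, 50),
                      schedule = list(list(mode = "clonal", generations = 3)),
                      seed = s)
    cfg0 <- small_cfg(N_recipient = 10, mu = 0, init_freq = rep(0.3, 50),
                      schedule = list(list(mode = "clonal", generations = 0)),
                      seed = s)
    parents <- key(run_forward(cfg0, keep_state = TRUE)[[1]]$final_state)
    offspring <- key(run_forward(cfg1, keep_state = TRUE)[[1]]$final_state)
    expect_true(all(offspring %in% parents))
  }
})

test_that("hybridization makes F1s heterozygous at donor-fixed sites", {
  cfg <- small_cfg(n_sites = 40, n_donor_sites = 40, hybrid_fraction = 0.5,
                   N_recipient = 20,
                   schedule = list(list(mode = "clonal", generations = 0)))
  cfg$schedule <- list(list(mode = "outcrossing", generations = 0))
  res <- run_forward(cfg, keep_state = TRUE)
  st <- res[[1]]$final_state
  tr <- res[[1]]$trajectory
  # copies right after the pulse = n_F1 x donor-fixed sites
  expect_equal(tr$total_introgressed_copies[1], 10 * 40)
  f1 <- which(rowSums((st$H1 != 0L) & st$O1) > 0)
  expect_equal(length(f1), 10L)
  expect_true(all(st$H1[f1, ] != 0L))
  expect_true(all(st$H2[f1, ] == 0L))   # recipient had no donor alleles
  expect_error(
    run_forward(small_cfg(hybrid_fraction = 2)), "hybrid_fraction")
})

test_that("origin flags change only through reproduction", {
  cfg <- small_cfg(n_sites = 30, n_donor_sites = 30, hybrid_fraction = 0.4,
                   N_recipient = 20, mu = 0,
                   schedule = list(list(mode = "outcrossing", generations = 15)),
                   record_every = 1)
  res <- run_forward(cfg)
  tr <- res[[1]]$trajectory
  # neutral, mu = 0: copies can drift but never exceed the theoretical cap
  expect_true(all(tr$total_introgressed_copies <= 2 * 20 * 30))
  # and no copies appear from nowhere after loss
  if (any(tr$total_introgressed_copies == 0)) {
    first0 <- min(which(tr$total_introgressed_copies == 0))
    expect_true(all(tr$total_introgressed_copies[first0:nrow(tr)] == 0))
  }
})

test_that("mu = 0 loses heterozygosity in the long run in both modes", {
  for (mode in c("outcrossing", "clonal")) {
    cfg <- small_cfg(N_recipient = 20, mu = 0, init_freq = rep(0.5, 50),
                     schedule = list(list(mode = mode, generations = 300)),
                     record_every = 50, replicates = 3, seed = 9)
    res <- run_forward(cfg)
    h0 <- mean(vapply(res, function(r)
      r$trajectory$mean_heterozygosity[1], numeric(1)))
    h1 <- mean(vapply(res, function(r)
      utils::tail(r$trajectory$mean_heterozygosity, 1), numeric(1)))
    expect_lt(h1, h0)
  }
})

test_that("clonal heterozygosity accumulates with mutation on", {
  cfg <- small_cfg(N_recipient = 20, mu = 2e-7, n_sites = 80,
                   schedule = list(list(mode = "clonal", generations = 2000)),
                   record_every = 25, replicates = 6, seed = 4)
  res <- run_forward(cfg)
  at <- function(r, g) {
    tr <- r$trajectory
    tr$mean_heterozygosity[which.min(abs(tr$generation - g))]
  }
  wins <- sum(vapply(res, function(r)
    at(r, 2000) > at(r, 500) && at(r, 500) > at(r, 50), logical(1)))
  expect_gte(wins, 5)
})

test_that("configuration validation rejects bad schedules and snapshots", {
  expect_error(small_cfg(snapshot_generations = 100), "beyond the schedule")
  expect_error(small_cfg(schedule = list(list(mode = "budding",
                                              generations = 5))),
               "modes")
  expect_error(small_cfg(mu = -1), "rates")
})

test_that("modal frequency bin centres on multiples of ten percent", {
  expect_equal(modal_frequency_percent(c(0.5, 0.5, 0.49, 0.52)), 50)
  expect_equal(modal_frequency_percent(c(0.98, 1, 0.97)), 100)
  expect_equal(modal_frequency_percent(rep(0.049, 5)), 0)
})

test_that("plateau detection finds sustained equilibria, not troughs", {
  g <- seq(0, 1000, by = 10)
  # dips at 200 then rises to a plateau from 600
  v <- ifelse(g < 200, 1000 - 2 * g,
              ifelse(g < 600, 600 + 2 * (g - 200), 1400))
  tr <- data.frame(generation = g, x = v)
  p <- detect_plateau(tr, column = "x")
  expect_gt(p, 600)
  # absorbed at zero counts as a plateau
  tr0 <- data.frame(generation = g, x = ifelse(g < 100, 100 - g, 0))
  expect_false(is.na(detect_plateau(tr0, column = "x")))
  # still-changing series has no plateau
  trc <- data.frame(generation = g, x = g^2 + 1)
  expect_true(is.na(detect_plateau(trc, column = "x")))
})
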