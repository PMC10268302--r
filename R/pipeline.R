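## End-to-end orchestration: synth -> stats -> abba -> load -> simulate,
## with a run manifest for reproducibility.  Each stage writes TSVs under
## the output directory and is skipped when its outputs already exist
## (partial re-runs); identical config + seed give identical numerical
## outputs.

pipeline_defaults <- function() {
  list(
    stages = c("synth", "stats", "abba", "load", "simulate"),
    scenario = list(),
    data = NULL,  # optional external inputs: vcf, popmap, truth, effects
    windows = list(size = 50000, min_snps = 30),
    trio = list(P1 = "table", P2 = "wine", P3 = "EU", O = "OUT"),
    tree = "(((wine,table),ME2),ME1,EU);",
    load = list(n_controls = 20, donor_min = 0.2, ref_max = 0),
    sim = list(N_recipient = 100, n_sites = 200, n_donor_sites = 60,
               hybrid_fraction = 0.1, replicates = 2,
               schedule = list(list(mode = "outcrossing", generations = 10),
                               list(mode = "clonal", generations = 200)))
  )
}

validate_pipeline_config <- function(config) {
  defaults <- pipeline_defaults()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, config)
  # modifyList skips unnamed list elements; schedules are replaced wholesale
  if (!is.null(config$sim$schedule)) cfg$sim$schedule <- config$sim$schedule
  if (!is.null(cfg$data)) {
    for (f in c("vcf", "popmap")) {
      if (is.null(cfg$data[[f]]))
        stopf("config field 'data.%s' is required when 'data' is given", f)
      if (!file.exists(cfg$data[[f]]))
        stopf("config field 'data.%s': file not found: %s", f, cfg$data[[f]])
    }
  }
  bad <- setdiff(cfg$stages, pipeline_defaults()$stages)
  if (length(bad)) stopf("config field 'stages': unknown stage(s) %s",
                         paste(bad, collapse = ", "))
  if (cfg$windows$size <= 0) stopf("config field 'windows.size' must be > 0")
  cfg
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis pipeline
#'
#' Executes the configured stages in dependency order on a synthetic
#' scenario (or user-supplied VCF + popmap), writing one TSV per statistic
#' plus a JSON run manifest.  Stages whose outputs already exist are skipped
#' unless `overwrite = TRUE`.
#'
#' @param config Named list overriding the pipeline defaults; unknown fields
#'   raise a schema error naming the field.  May also be a path to a YAML
#'   file.
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed governing every stochastic stage.
#' @param overwrite Recompute stages whose outputs exist.
#' @return The run manifest, invisibly (also written as `manifest.json`).
#' @export
run_pipeline <- function(config = list(), out_dir, seed = 1,
                         overwrite = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validate_pipeline_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t0 <- Sys.time()
  outputs <- character()
  emit <- function(df, name) {
    p <- file.path(out_dir, name)
    write_tsv(df, p)
    outputs <<- c(outputs, p)
    p
  }
  done <- function(name) !overwrite && file.exists(file.path(out_dir, name))

  ## ---- synth ----
  scen <- do.call(scenario_config, utils::modifyList(cfg$scenario,
                                                     list(seed = seed)))
  if ("synth" %in% cfg$stages && is.null(cfg$data)) {
    if (!done("data.vcf")) {
      ds <- generate_dataset(scen, out_dir = out_dir)
    } else {
      ds <- generate_dataset(scen)  # regenerate in memory, files untouched
    }
    outputs <- c(outputs, file.path(out_dir, c("data.vcf", "popmap.tsv",
                                               "truth.bed", "effects.tsv")))
  } else {
    gm <- read_vcf(cfg$data$vcf)
    ds <- list(gm = gm, popmap = read_popmap(cfg$data$popmap),
               truth = if (!is.null(cfg$data$truth)) read_bed(cfg$data$truth)
                       else region_set(),
               effects = if (!is.null(cfg$data$effects))
                           read_effects(cfg$data$effects) else NULL,
               contig_lengths = stats::setNames(
                 as.numeric(tapply(gm$pos, gm$chrom, max)) + 1,
                 sort(unique(gm$chrom))))
  }

  pol <- polarize_by_outgroup(ds$gm, names(ds$popmap)[ds$popmap == "OUT"])
  windows <- make_windows(ds$contig_lengths, cfg$windows$size,
                          min_snps = cfg$windows$min_snps, gm = pol)
  groups <- setdiff(unique(ds$popmap), "OUT")

  ## ---- stats ----
  if ("stats" %in% cfg$stages && !done("heterozygosity.tsv")) {
    het <- sample_heterozygosity(ds$gm)
    emit(data.frame(sample = names(het),
                    group = unname(ds$popmap[names(het)]),
                    heterozygosity = unname(het)), "heterozygosity.tsv")
    pi_tab <- do.call(rbind, lapply(groups, function(g) {
      x <- window_pi(pol, ds$popmap, g, windows)
      x$group <- g
      x
    }))
    emit(pi_tab, "pi.tsv")
    dxy_w <- window_dxy(pol, ds$popmap, "wine", "EU", windows)
    dxy_t <- window_dxy(pol, ds$popmap, "table", "EU", windows)
    emit(cbind(dxy_w[1:3], dxy_wine_eu = dxy_w$dxy, dxy_table_eu = dxy_t$dxy,
               dxy_diff = dxy_difference(dxy_w, dxy_t)$dxy_diff),
         "dxy_contrast.tsv")
    prs <- utils::combn(groups, 2)
    fst_tab <- do.call(rbind, lapply(seq_len(ncol(prs)), function(i) {
      data.frame(group_a = prs[1, i], group_b = prs[2, i],
                 fst = global_fst(pol, ds$popmap, prs[1, i], prs[2, i]))
    }))
    emit(fst_tab, "fst_global.tsv")
    emit(window_pbs(pol, ds$popmap, "wine", "ME2", "EU", windows), "pbs_wine.tsv")
    emit(pairwise_pi_hat(ds$gm), "ibd.tsv")
  }

  ## ---- abba ----
  if ("abba" %in% cfg$stages && !done("fd_windows.tsv")) {
    fq <- trio_site_freqs(pol, ds$popmap, unlist(cfg$trio))
    tr <- window_abba_baba(fq, windows)
    emit(tr, "fd_windows.tsv")
    fb <- fbranch(pol, ds$popmap, cfg$tree, cfg$trio$O)
    fb_df <- data.frame(branch = rownames(fb$fb), fb$fb, check.names = FALSE)
    emit(fb_df, "fbranch.tsv")
  }

  ## ---- load ----
  if ("load" %in% cfg$stages && !is.null(ds$effects) && nrow(ds$truth) &&
      !done("load.tsv")) {
    tract_u <- merge_regions(region_set(ds$truth$chrom, ds$truth$start,
                                        ds$truth$end, label = "introgressed"),
                             max_gap = 0)
    tract_u$label <- "introgressed"
    bg <- complement_regions(tract_u, ds$contig_lengths, label = "background")
    strata <- as_region_set(rbind(tract_u[c("chrom", "start", "end", "label")],
                                  bg[c("chrom", "start", "end", "label")]))
    lt <- load_per_individual(pol, ds$effects, strata)
    emit(lt, "load.tsv")
    ratio <- load_density_ratio(lt, "introgressed", "background")
    ctrl <- random_control_regions(ds$contig_lengths, tract_u,
                                   n_reps = cfg$load$n_controls, seed = seed)
    ctrl_ratio <- vapply(ctrl, function(cr) {
      cr$label <- "control"
      s2 <- as_region_set(rbind(cr[c("chrom", "start", "end", "label")],
                                bg[c("chrom", "start", "end", "label")]))
      suppressWarnings(
        load_density_ratio(load_per_individual(pol, ds$effects, s2),
                           "control", "background")[["het_ratio"]])
    }, numeric(1))
    emit(data.frame(statistic = names(ratio), value = as.numeric(ratio),
                    control_q025 = unname(stats::quantile(ctrl_ratio, 0.025,
                                                          na.rm = TRUE)),
                    control_q975 = unname(stats::quantile(ctrl_ratio, 0.975,
                                                          na.rm = TRUE))),
         "load_ratio.tsv")
    spec <- introgressed_allele_spectrum(pol, ds$popmap, "EU",
                                         c("ME1", "ME2"), "wine", tract_u,
                                         donor_min = cfg$load$donor_min,
                                         ref_max = cfg$load$ref_max)
    if (nrow(spec$bins)) emit(spec$bins, "introgressed_spectrum.tsv")
  }

  ## ---- simulate ----
  if ("simulate" %in% cfg$stages && !done("sim_trajectory.tsv")) {
    sim_args <- cfg$sim
    sim_args$seed <- seed
    sim_cfg <- do.call(sim_config, sim_args)
    arms <- introgression_experiment(sim_cfg)
    traj <- do.call(rbind, lapply(names(arms), function(arm) {
      do.call(rbind, lapply(seq_along(arms[[arm]]), function(i) {
        x <- arms[[arm]][[i]]$trajectory
        x$arm <- arm
        x$replicate <- i
        x
      }))
    }))
    emit(traj, "sim_trajectory.tsv")
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("clonintro")),
    seed = seed,
    config_hash = config_hash(cfg),
    stages = cfg$stages,
    outputs = basename(unique(outputs)),
    checksums = as.list(tools::md5sum(unique(outputs[file.exists(outputs)]))),
    wall_clock_sec = as.numeric(difftime(Sys.time(), t0, units = "secs")))
  names(manifest$checksums) <- basename(names(manifest$checksums))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, force = TRUE,
                              digits = NA), tmp)
  unname(tools::md5sum(tmp))
}
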