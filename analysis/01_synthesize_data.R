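#!/usr/bin/env Rscript

# Stage 1 — build the synthetic study system.
#
# Five populations (two Middle-East-like wild groups, a low-diversity
# EU-like wild donor, table- and wine-grape analogs with a recent clonal
# history) plus an outgroup, with a donor pulse five-fold stronger into the
# wine analog, and ground-truth donor-ancestry tracts.  Also emits a simple
# gene annotation used by the scan stage.

suppressPackageStartupMessages(library(clonintro))

seed <- 1
out <- "results/dataset"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

ds <- generate_dataset(scenario_config(seed = seed), out_dir = out)

# toy gene annotation: 2-8 kb intervals tiled at random over the contig
genes <- local({
  set.seed(seed)
  L <- ds$contig_lengths[[1]]
  starts <- sort(sample.int(L - 8000L, 150))
  region_set(names(ds$contig_lengths)[1], starts,
             pmin(starts + sample(2000:8000, 150, replace = TRUE), L),
             label = "gene")
})
write_bed(genes, file.path(out, "genes.bed"))

message(sprintf("emitted %d biallelic SNPs for %d samples (%d groups)",
                n_sites(ds$gm), length(ds$gm$samples),
                length(unique(ds$popmap))))
message(sprintf("truth: %d donor-ancestry tracts covering %.1f%% of the genome x cultivated samples",
                nrow(ds$truth),
                100 * sum(ds$truth$end - ds$truth$start) /
                  (ds$contig_lengths[[1]] * sum(ds$popmap %in% c("wine", "table")))))
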