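#!/usr/bin/env Rscript

# Stage 3 — ABBA-BABA introgression scan.
#
# Windowed D/fd/fdM for both cultivated analogs as the candidate recipient,
# the f-branch matrix over the population tree, top-5% fd regions, gene
# counts per fd bin, merging of nearby candidate regions, and overlap of
# candidate introgressed regions with PBS-selected regions.

suppressPackageStartupMessages(library(clonintro))

out <- "results"
ds_dir <- file.path(out, "dataset")
gm <- read_vcf(file.path(ds_dir, "data.vcf"))
popmap <- read_popmap(file.path(ds_dir, "popmap.tsv"))
truth <- read_bed(file.path(ds_dir, "truth.bed"))
genes <- read_bed(file.path(ds_dir, "genes.bed"))
contig_lengths <- c(chr1 = 1e6)

pol <- polarize_by_outgroup(gm, names(popmap)[popmap == "OUT"])
w <- make_windows(contig_lengths, 50000, min_snps = 25, gm = pol)

scan <- function(p1, p2) {
  fq <- trio_site_freqs(pol, popmap, c(P1 = p1, P2 = p2, P3 = "EU", O = "OUT"))
  window_abba_baba(fq, w)
}
tr_wine <- scan("table", "wine")
tr_table <- scan("wine", "table")
write.table(tr_wine, file.path(out, "fd_wine.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(tr_table, file.path(out, "fd_table.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("mean fd: wine as recipient %.3f, table as recipient %.3f",
                mean(tr_wine$fd, na.rm = TRUE),
                mean(tr_table$fd, na.rm = TRUE)))
jk <- d_jackknife(tr_wine)
message(sprintf("genome-wide D (wine) = %.3f +/- %.3f (block jackknife)",
                jk$D, jk$se))

fb <- fbranch(pol, popmap, "((((wine,table),ME2),ME1),EU);", "OUT")
fb_df <- data.frame(branch = rownames(fb$fb), fb$fb, check.names = FALSE)
write.table(fb_df, file.path(out, "fbranch.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
message(sprintf("fb(wine, donor=EU) = %.3f ; fb(table, donor=EU) = %.3f",
                fb$fb["wine", "EU"], fb$fb["table", "EU"]))

top <- top_quantile_regions(tr_wine, q = 0.05)
write_bed(top, file.path(out, "top_fd_regions.bed"))

bins <- genes_per_fd_bin(tr_wine, genes, bin_edges = seq(0, 1, by = 0.2))
write.table(bins, file.path(out, "genes_per_fd_bin.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)

# merge candidate regions separated by < 50 kb, as for supergene calling
merged <- merge_regions(top, max_gap = 50000)
write_bed(merged, file.path(out, "top_fd_regions_merged.bed"))
message(sprintf("top-5%% fd windows: %d; after <50 kb merging: %d regions (%d-%d kb)",
                nrow(top), nrow(merged),
                round(min(merged$end - merged$start) / 1000),
                round(max(merged$end - merged$start) / 1000)))

# overlap of candidate introgressed regions with PBS-selected regions
pbs_tab <- read.table(file.path(out, "pbs_wine.tsv"), header = TRUE)
sel_thr <- quantile(pbs_tab$pbs, 0.95, na.rm = TRUE)
sel <- pbs_tab[!is.na(pbs_tab$pbs) & pbs_tab$pbs >= sel_thr, ]
selected <- region_set(sel$chrom, sel$start, sel$end, label = "selected")
ov <- region_overlap_summary(merged, selected)
message(sprintf("%d of %d merged candidate regions overlap top-5%% PBS regions (%.0f%% of bases)",
                ov$n_overlapping, nrow(merged),
                100 * ov$fraction_a_overlapped))

# sanity against ground truth: fd over truth tracts vs background
wine_tracts <- truth[truth$label %in% names(popmap)[popmap == "wine"], ]
ctr <- fd_tract_contrast(tr_wine, wine_tracts, sum(popmap == "wine"))
message(sprintf("fd over truth tracts %.3f vs background %.3f",
                ctr$fd_tract, ctr$fd_background))
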