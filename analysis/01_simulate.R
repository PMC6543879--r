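#!/usr/bin/env Rscript

# Stage 1: generate the synthetic study inputs with known truth.
#
# Two datasets are produced under results/data/:
#  * a CDS-like polarized SFS dataset (neutral ancestral-repeat reference +
#    focal spectra) simulated under the bimodal 2-class DFE with realistic
#    polarization error, plus a noncoding-like dataset under the published
#    gamma DFE;
#  * a toy genome (3 chromosomes x 2 Mb here; scale up via config) with a
#    diversity trough near exons and per-chromosome cubic genetic maps,
#    written as VCF/GFF3/BED/TSV for the scan stages.

suppressMessages(library(indeldfe))

cfg <- run_config(seed = 1L)
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
write_config(cfg, file.path(out, "config.json"))

cds_truth <- synth_sfs_truth(
  theta_neutral = c(ins = 1.39e-4, del = 2.14e-4),
  focal = list(ins = list(gammas = c(-1.14, -801), thetas = c(4.92e-6, 1.34e-4)),
               del = list(gammas = c(-2.70, -649), thetas = c(8.32e-6, 2.06e-4))),
  eps = orientation_errors(0.0799, 0.0368), seed = cfg$seed)
cds <- simulate_sfs_dataset(cds_truth)
write_sfs_pair(cds$neutral, file.path(out, "cds_neutral_sfs.tsv"))
write_sfs_pair(cds$focal, file.path(out, "cds_focal_sfs.tsv"))

nc_truth <- synth_sfs_truth(seed = cfg$seed + 1L) # gamma-DFE defaults
nc <- simulate_sfs_dataset(nc_truth)
write_sfs_pair(nc$neutral, file.path(out, "noncoding_neutral_sfs.tsv"))
write_sfs_pair(nc$focal, file.path(out, "noncoding_focal_sfs.tsv"))

g_truth <- synth_genome_truth(n_chrom = 3L, chrom_len = 2e6,
                              exon_spacing = 250000L, tau = 25000,
                              seed = cfg$seed + 2L)
g <- simulate_genome(g_truth)
paths <- write_genome_files(g, file.path(out, "genome"))

cat("CDS-like dataset: neutral S =",
    sum(cds$neutral$ins$counts) + sum(cds$neutral$del$counts),
    ", focal S =", sum(cds$focal$ins$counts) + sum(cds$focal$del$counts), "\n")
cat("noncoding dataset: focal S =",
    sum(nc$focal$ins$counts) + sum(nc$focal$del$counts), "\n")
cat("toy genome:", nrow(g$variants), "variants on",
    length(g$chrom_lengths), "chromosomes ->", dirname(paths[["vcf"]]), "\n")
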