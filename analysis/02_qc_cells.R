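#!/usr/bin/env Rscript
# Stage 2: quality control and cell-type deconvolution.
#
# Drops probes failing the detection-p rule and SNPs failing missingness
# or within-group Hardy-Weinberg, then estimates leukocyte proportions by
# constrained projection onto the signature-probe reference profiles.

library(admixmeth)

cfg <- read_run_config("analysis/config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
out_dir <- file.path(cfg$output_dir, "qc")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest_tsv(file.path(data_dir, "manifest.tsv"))
beta <- read_beta_tsv(file.path(data_dir, "beta.tsv"), manifest)
det <- utils::read.delim(file.path(data_dir, "detection_p.tsv"),
                         check.names = FALSE)
beta$detection_p <- t(as.matrix(det[, -1L]))
sheet <- read_sample_sheet(file.path(data_dir, "sample_sheet.csv"))
geno <- read_dosage_tsv(file.path(data_dir, "dosages.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)

meth <- filter_probes(beta, cfg$qc$detection_p_cut, cfg$qc$max_fail_frac)
cat(sprintf("probe QC: %d -> %d probes (removed: %s)\n",
            nrow(manifest), ncol(meth$values),
            paste(attr(meth, "removed"), collapse = ", ")))

geno_qc <- qc_genotypes(geno, sheet$ethnicity, cfg$qc$miss_cut,
                        cfg$qc$hwe_cut)
cat(sprintf("genotype QC: %d -> %d SNPs\n", nrow(geno$snps),
            nrow(geno_qc$snps)))

# reference = true per-cell-type M profiles at the signature probes
sig <- intersect(truth$sets$signature, meth$probes$probe)
jj <- match(sig, truth$cpgs$probe)
prof <- t(sweep(as.matrix(truth$cell_delta)[jj, , drop = FALSE], 1L,
                truth$mu[jj], "+"))
rownames(prof) <- truth$cell_types
colnames(prof) <- sig
cells <- estimate_cell_proportions(meth, cell_reference(prof))

cells_true <- utils::read.delim(file.path(data_dir, "cells_true.tsv"))
mae <- mean(abs(cells$proportions -
                  as.matrix(cells_true[, truth$cell_types])))
cat(sprintf(
  "deconvolution on %d signature probes: mean |error| vs truth %.4f\n",
  length(sig), mae))

utils::write.table(
  data.frame(indiv = rownames(cells$proportions), cells$proportions,
             residual_norm = cells$residual_norm, check.names = FALSE),
  file.path(out_dir, "cells_estimated.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
write_beta_tsv(meth, file.path(out_dir, "beta_postqc.tsv"))
write_dosage_tsv(geno_qc, file.path(out_dir, "dosages_postqc.tsv"))
utils::write.table(attr(geno_qc, "removal_log"),
                   file.path(out_dir, "snp_removal_log.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
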