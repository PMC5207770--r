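#!/usr/bin/env Rscript
# Stage 3: global methylation structure and genotype PCs.
#
# Principal coordinates of the M-value Euclidean distances, omnibus
# associations of each coordinate with ethnicity and with global ancestry
# (covariate-adjusted), genotype PCA for fine-scale structure, and the
# recalculated-on-residuals check: after regressing methylation on
# ancestry, ancestry-driven coordinates should vanish.

library(admixmeth)

cfg <- read_run_config("analysis/config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
qc_dir <- file.path(cfg$output_dir, "qc")
out_dir <- file.path(cfg$output_dir, "structure")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest_tsv(file.path(data_dir, "manifest.tsv"))
meth <- read_beta_tsv(file.path(qc_dir, "beta_postqc.tsv"), manifest)
sheet <- read_sample_sheet(file.path(data_dir, "sample_sheet.csv"))
qdf <- utils::read.delim(file.path(data_dir, "global_ancestry.tsv"))
q <- as.matrix(qdf[, -1L]); rownames(q) <- qdf$indiv
cells <- utils::read.delim(file.path(qc_dir, "cells_estimated.tsv"))
cells_m <- as.matrix(cells[, c("Granulocyte", "Lymphocyte", "Monocyte")])

M <- as_m_matrix(meth)
covars <- covariate_design(sheet, cells_m)
eth <- factor(sheet$ethnicity)

pc <- pcoa(M, k = 10)
pc_eth <- associate_pc(pc$coordinates, eth, covars)
pc_anc <- associate_pc(pc$coordinates, compositional_columns(q, "EUR"),
                       cbind(covars, indicator_columns(eth, "ethnicity")))
cat("PC-ethnicity omnibus p:\n")
print(data.frame(pc = pc_eth$pc, p_ethnicity = signif(pc_eth$p, 2),
                 p_ancestry = signif(pc_anc$p, 2)))

gpca <- genotype_pca(read_dosage_tsv(file.path(qc_dir,
                                               "dosages_postqc.tsv")),
                     k = 10)
cat(sprintf("genotype PCA: top eigenvalue share %.2f\n",
            gpca$eigenvalues[1] / sum(gpca$eigenvalues)))

# residual workflow: remove ancestry, recompute coordinates
pc_resid <- pcoa(residualize(M, compositional_columns(q, "EUR")), k = 10)
pc_resid_eth <- associate_pc(pc_resid$coordinates, eth, covars)
cat(sprintf(
  "after residualizing on ancestry, %d of 10 coordinates remain associated with ethnicity at p < 0.005 (before: %d)\n",
  sum(pc_resid_eth$p < 0.005, na.rm = TRUE),
  sum(pc_eth$p < 0.005, na.rm = TRUE)))

wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
wt(data.frame(indiv = rownames(pc$coordinates), pc$coordinates),
   "pcoa_scores.tsv")
wt(data.frame(component = seq_along(pc$eigenvalues),
              eigenvalue = pc$eigenvalues), "pcoa_scree.tsv")
wt(data.frame(indiv = sheet$indiv, gpca$scores), "genotype_pca.tsv")
wt(cbind(pc_eth, p_ancestry = pc_anc$p), "pc_associations.tsv")
wt(pc_resid_eth, "pc_associations_residualized.tsv")
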