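#!/usr/bin/env Rscript
# Stage 4: epigenome-wide association scans.
#
# Per-CpG omnibus tests of ethnicity (3 df across the four groups), the
# ancestry-adjusted ethnicity scan with the stability screen, the
# classification of ethnicity hits into remains / explained / unstable,
# the 2-df global-ancestry scan with per-component attribution, the
# fine-structure (genotype PCs 3-10) adjustment, and the non-linearity
# screen at the surviving hits.

library(admixmeth)

cfg <- read_run_config("analysis/config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
qc_dir <- file.path(cfg$output_dir, "qc")
out_dir <- file.path(cfg$output_dir, "ewas")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest_tsv(file.path(data_dir, "manifest.tsv"))
meth <- read_beta_tsv(file.path(qc_dir, "beta_postqc.tsv"), manifest)
sheet <- read_sample_sheet(file.path(data_dir, "sample_sheet.csv"))
qdf <- utils::read.delim(file.path(data_dir, "global_ancestry.tsv"))
q <- as.matrix(qdf[, -1L])
cells <- utils::read.delim(file.path(qc_dir, "cells_estimated.tsv"))
cells_m <- as.matrix(cells[, c("Granulocyte", "Lymphocyte", "Monocyte")])

M <- as_m_matrix(meth)
covars <- covariate_design(sheet, cells_m)
eth <- factor(sheet$ethnicity)
anc <- compositional_columns(q, ref = "EUR")
alpha <- cfg$thresholds$alpha

scan_eth <- ewas_ethnicity(M, eth, covars, alpha = alpha)
scan_adj <- ewas_ethnicity(M, eth, covars, ancestry = anc, alpha = alpha)
unstable <- scan_stability(M, eth, covars, anc)
cls <- classify_adjustment(scan_eth, scan_adj, unstable)
counts <- attr(cls, "counts")
cat(sprintf(
  "ethnicity scan: %d/%d CpGs at p < %.2g; after ancestry adjustment %d remain, %d explained, %d unstable\n",
  sum(scan_eth$significant), nrow(scan_eth), attr(scan_eth, "threshold"),
  counts["remains"], counts["explained"], counts["unstable"]))

scan_anc <- ewas_ancestry(M, q, eth, covars, alpha = alpha)
tab <- table(scan_anc$driven_by[scan_anc$significant])
cat(sprintf("ancestry scan: %d CpGs (%s)\n", sum(scan_anc$significant),
            paste(names(tab), tab, sep = "=", collapse = ", ")))

# fine-structure adjustment: genotype PCs 3-10 added to the adjusted model
gpc <- as.matrix(utils::read.delim(
  file.path(cfg$output_dir, "structure", "genotype_pca.tsv"))[, -1L])
fine <- gpc[, 3:10]
colnames(fine) <- paste0("finePC", 3:10)
remains <- cls$probe[cls$class == "remains"]
if (length(remains)) {
  scan_fine <- ewas_ethnicity(M[, remains, drop = FALSE], eth,
                              cbind(covars, fine), ancestry = anc,
                              alpha = alpha)
  thr <- attr(scan_eth, "threshold")
  cat(sprintf(
    "fine-structure adjustment: %d of %d remaining hits survive PCs 3-10\n",
    sum(scan_fine$p < thr), length(remains)))
} else scan_fine <- NULL

# non-linearity screen at the remaining hits (spline and polynomial)
nl <- do.call(rbind, lapply(remains, function(pr) {
  sp <- nonlinearity_test(M[, pr], q[, "NAM"], covars, ethnicity = eth,
                          method = "spline")
  po <- nonlinearity_test(M[, pr], q[, "NAM"], covars, ethnicity = eth,
                          method = "poly")
  data.frame(probe = pr, p_spline = sp$p_nonlinear,
             p_poly = po$p_nonlinear,
             p_ethnicity_given_spline = sp$p_ethnicity)
}))
if (!is.null(nl)) {
  cat(sprintf(
    "non-linearity at remaining hits: %d (spline) and %d (poly) of %d at p < 0.05; ethnicity survives the spline block at %d\n",
    sum(nl$p_spline < 0.05), sum(nl$p_poly < 0.05), nrow(nl),
    sum(nl$p_ethnicity_given_spline < 0.05)))
}

wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
wt(scan_eth, "ewas_ethnicity.tsv")
wt(scan_adj, "ewas_ethnicity_adjusted.tsv")
wt(cls, "classification.tsv")
wt(scan_anc, "ewas_ancestry.tsv")
if (!is.null(scan_fine)) wt(scan_fine, "ewas_fine_structure.tsv")
if (!is.null(nl)) wt(nl, "nonlinearity.tsv")
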