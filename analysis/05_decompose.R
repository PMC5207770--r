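#!/usr/bin/env Rscript
# Stage 5: variance partitioning, mediation, and the Duffy-locus workup.
#
# At every ethnicity hit: joint PVE of ethnicity + global ancestry and the
# ancestry share (the Table-2-style medians/IQRs). At every ancestry hit:
# local vs global ancestry partition using tract-derived local dosage at
# the CpG. Mediation of the ethnicity-associated methylation coordinates
# by Native American ancestry (Mexican vs Puerto Rican contrast). Finally
# the fixed-difference locus: admixture mapping, cis-SNP scan, and the
# conditional test.

library(admixmeth)

cfg <- read_run_config("analysis/config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
qc_dir <- file.path(cfg$output_dir, "qc")
ewas_dir <- file.path(cfg$output_dir, "ewas")
out_dir <- file.path(cfg$output_dir, "decomp")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

manifest <- read_manifest_tsv(file.path(data_dir, "manifest.tsv"))
meth <- read_beta_tsv(file.path(qc_dir, "beta_postqc.tsv"), manifest)
sheet <- read_sample_sheet(file.path(data_dir, "sample_sheet.csv"))
qdf <- utils::read.delim(file.path(data_dir, "global_ancestry.tsv"))
q <- as.matrix(qdf[, -1L])
cells <- utils::read.delim(file.path(qc_dir, "cells_estimated.tsv"))
cells_m <- as.matrix(cells[, c("Granulocyte", "Lymphocyte", "Monocyte")])
tracts <- read_tracts_bed(file.path(data_dir, "tracts.bed.tsv"),
                          labels = c("AFR", "EUR", "NAM"))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)
scan_eth <- utils::read.delim(file.path(ewas_dir, "ewas_ethnicity.tsv"))
scan_anc <- utils::read.delim(file.path(ewas_dir, "ewas_ancestry.tsv"))

M <- as_m_matrix(meth)
covars <- covariate_design(sheet, cells_m)
eth <- factor(sheet$ethnicity)

fmt <- function(x) sprintf("%.1f%% (IQR %.1f%% to %.1f%%)",
                           100 * median(x, na.rm = TRUE),
                           100 * quantile(x, 0.25, na.rm = TRUE),
                           100 * quantile(x, 0.75, na.rm = TRUE))

hits <- scan_eth$probe[scan_eth$significant]
parts <- do.call(rbind, lapply(hits, function(pr) {
  vp <- joint_partition(M[, pr], eth, q, covars)
  data.frame(probe = pr, joint = vp$joint, ethnicity = vp$ethnicity,
             ancestry = vp$ancestry, ancestry_share = vp$ancestry_share,
             stable = vp$stable)
}))
cat(sprintf(
  "at %d ethnicity hits: joint PVE %s; ethnicity %s; ancestry %s; ancestry share of joint %s\n",
  nrow(parts), fmt(parts$joint), fmt(parts$ethnicity), fmt(parts$ancestry),
  fmt(parts$ancestry_share)))

anc_hits <- scan_anc$probe[scan_anc$significant]
pos_gen <- truth$cpgs$pos_gen[match(anc_hits, truth$cpgs$probe)]
lg <- do.call(rbind, lapply(seq_along(anc_hits), function(i) {
  dos <- local_dosage_at(tracts, pos_gen[i])
  vp <- local_global_partition(M[, anc_hits[i]], dos, q, covars)
  data.frame(probe = anc_hits[i], joint = vp$joint, local = vp$local,
             global = vp$global, local_share = vp$local_share)
}))
if (!is.null(lg)) {
  cat(sprintf(
    "at %d ancestry hits: local-ancestry PVE %s, local share of the joint local+global PVE %s\n",
    nrow(lg), fmt(lg$local), fmt(lg$local_share)))
}

# mediation of ethnicity-associated methylation PCs by NAM ancestry
pc <- utils::read.delim(file.path(cfg$output_dir, "structure",
                                  "pcoa_scores.tsv"))
pc_assoc <- utils::read.delim(file.path(cfg$output_dir, "structure",
                                        "pc_associations.tsv"))
in_pair <- sheet$ethnicity %in% c("Mexican", "PuertoRican")
med <- lapply(pc_assoc$pc[pc_assoc$p < 0.05], function(pcn) {
  res <- mediate(pc[in_pair, pcn],
                 treatment = as.numeric(
                   sheet$ethnicity[in_pair] == "Mexican"),
                 mediator = q[in_pair, "NAM"],
                 covariates = covars[in_pair, , drop = FALSE],
                 n_sims = cfg$mediation$n_sims, seed = cfg$seed)
  cat(sprintf(
    "%s: proportion of the ethnicity association mediated by NAM ancestry %.0f%% (95%% CI %.0f%%-%.0f%%, p=%.3g)\n",
    pcn, 100 * res$prop_mediated, 100 * res$prop_ci[1],
    100 * res$prop_ci[2], res$acme_p))
  list(pc = pcn, acme = res$acme, ade = res$ade, total = res$total,
       prop_mediated = res$prop_mediated, prop_ci = res$prop_ci,
       p = res$acme_p)
})

# the Duffy-like fixed-difference locus: the CpG whose driving SNP sits
# exactly duffy_gap_bp away
duffy <- NULL
geno <- read_dosage_tsv(file.path(data_dir, "dosages.tsv"))
j_fixed <- which(vapply(seq_len(nrow(truth$cpgs)), function(j) {
  !is.na(truth$meqtl_snp[j]) &&
    isTRUE(all.equal(abs(truth$cpgs$pos_bp[j] -
      geno$snps$pos_bp[match(truth$meqtl_snp[j], geno$snps$snp)]),
      cfg$genome$duffy_gap_bp))
}, logical(1)))[1]
if (!is.na(j_fixed)) {
  pr <- truth$cpgs$probe[j_fixed]
  dos <- local_dosage_at(tracts, truth$cpgs$pos_gen[j_fixed])
  am <- admixture_map(M[, pr], dos, covars)
  cs <- cis_scan(M[, pr], geno, truth$cpgs$pos_bp[j_fixed],
                 window_bp = 10000, covariates = covars,
                 local_dosage = dos)
  afr <- am$effects[am$effects$ancestry == "AFR", ]
  cat(sprintf(
    "Duffy-like locus %s: +%.2f M per African haplotype (%.1f-fold), causal SNP ranked %d/%d in the 10 kb window, ancestry p %.2g -> %.2g after conditioning\n",
    pr, afr$beta, m_to_fold(afr$beta),
    match(truth$meqtl_snp[j_fixed], cs$table$snp), nrow(cs$table),
    cs$conditional$ancestry_p_unconditional,
    cs$conditional$ancestry_p_given_snp))
  duffy <- list(probe = pr, snp = truth$meqtl_snp[j_fixed],
                afr_haplotype_effect = afr$beta,
                fold = m_to_fold(afr$beta),
                snp_rank = match(truth$meqtl_snp[j_fixed], cs$table$snp),
                ancestry_p = cs$conditional$ancestry_p_unconditional,
                ancestry_p_given_snp = cs$conditional$ancestry_p_given_snp,
                abolished = cs$conditional$abolished)
}

wt <- function(df, f) utils::write.table(df, file.path(out_dir, f),
                                         sep = "\t", quote = FALSE,
                                         row.names = FALSE)
wt(parts, "partitions_ethnicity.tsv")
if (!is.null(lg)) wt(lg, "partitions_local_global.tsv")
jsonlite::write_json(list(mediation = med, duffy = duffy),
                     file.path(out_dir, "mediation_duffy.json"),
                     auto_unbox = TRUE, digits = 10, pretty = TRUE)
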