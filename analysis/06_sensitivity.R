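#!/usr/bin/env Rscript
# Stage 6: sensitivity analyses and exposure-set enrichment.
#
# Down-sampling (does the ancestry scan retain hits at roughly half the
# cohort?), the independent effect of recruitment site adjusted for
# ethnicity, and enrichment of the environmentally-shifted CpG set among
# the ethnicity-associated loci.

library(admixmeth)

cfg <- read_run_config("analysis/config.yaml")
data_dir <- file.path(cfg$output_dir, "data")
ewas_dir <- file.path(cfg$output_dir, "ewas")
out_dir <- file.path(cfg$output_dir, "sensitivity")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

scan_eth <- utils::read.delim(file.path(ewas_dir, "ewas_ethnicity.tsv"))
truth <- jsonlite::read_json(file.path(data_dir, "truth.json"),
                             simplifyVector = TRUE)

# down-sampling to roughly half the cohort
n_full <- sum(cfg$cohort$n_mexican, cfg$cohort$n_puerto_rican,
              cfg$cohort$n_mixed, cfg$cohort$n_other)
half <- suppressMessages(downsample_rerun(cfg, n_target = n_full %/% 2,
                                          seed = cfg$seed + 1L))
cat(sprintf(
  "down-sampling %d -> %d: ethnicity hits %d -> %d, ancestry hits -> %d\n",
  n_full, n_full %/% 2, sum(scan_eth$significant),
  half$hits$ethnicity, half$hits$ancestry))

# recruitment site adjusted for ethnicity (no site effect is simulated,
# so Bonferroni hits should be ~0)
site <- suppressMessages(site_sensitivity(cfg))
cat(sprintf("recruitment site: %d Bonferroni hits at p < %.2g\n",
            site$n_hits, site$threshold))

# enrichment of the environmentally-shifted candidate set
p_map <- stats::setNames(scan_eth$p, scan_eth$probe)
cand <- intersect(truth$sets$env, scan_eth$probe)
enr <- enrichment(scan_eth$probe[scan_eth$significant], cand,
                  scan_eth$probe, p_map, rate0 = cfg$thresholds$nominal)
cat(sprintf(
  "exposure set: %d/%d nominal (%.1f%%), binomial p %.3g; overlap %d with the hit set, hypergeometric p %.3g\n",
  enr$n_nominal, enr$n_candidates, 100 * enr$nominal_rate, enr$binom_p,
  enr$overlap, enr$hyper_p))

jsonlite::write_json(
  list(downsample = half$hits, site_hits = site$n_hits,
       site_threshold = site$threshold, enrichment = unclass(enr)),
  file.path(out_dir, "sensitivity.json"), auto_unbox = TRUE, digits = 10,
  pretty = TRUE)
utils::write.table(site$scan, file.path(out_dir, "site_scan.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)
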