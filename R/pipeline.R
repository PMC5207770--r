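# Config-driven end-to-end orchestration: simulate -> QC -> cell estimation
# -> structure -> EWAS -> classification -> variance partitioning ->
# mediation -> enrichment -> report. Each stage logs one structured line
# (shapes, thresholds, seed) and writes its outputs under the configured
# directory; the JSON report is deterministic given the seed.

#' Default run configuration
#'
#' Nested list of every tunable: cohort sizes, genome and effect-grid
#' parameters of the simulator, QC thresholds, and significance levels.
#' Values can be overridden via [read_run_config()] or by modifying the
#' returned list.
#'
#' @return Named nested list.
#' @export
default_config <- function() {
  list(
    seed = 1L,
    output_dir = "results/pipeline",
    cohort = list(n_mexican = 276L, n_puerto_rican = 220L,
                  n_mixed = 16L, n_other = 61L, concentration = 30),
    genome = list(n_snps = 200L, genetic_length = 2, generations = 8,
                  duffy = TRUE, duffy_pos_gen = 0.5, duffy_gap_bp = 212L,
                  duffy_beta = 1.35),
    effects = list(n_cpgs = 500L, n_meqtl = 40L, n_theta = 80L,
                   n_env = 80L, n_signature = 60L, meqtl_beta = 1.35,
                   theta_contrast = 0.5, env_shift = 0.5, noise_sd = 0.45,
                   batch_sd = 0.05, fail_rate = 0.002),
    qc = list(detection_p_cut = 0.01, max_fail_frac = 0.01,
              miss_cut = 0.05, hwe_cut = 1e-6),
    thresholds = list(alpha = 0.05, nominal = 0.05),
    mediation = list(n_sims = 1000L)
  )
}

#' Read a YAML run configuration
#'
#' Reads a YAML file and merges it over [default_config()] (file entries
#' win; missing entries keep their defaults).
#'
#' @param path YAML file path.
#' @return Config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  modify_list_deep(default_config(), user)
}

modify_list_deep <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(user[[nm]])) {
      modify_list_deep(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

log_stage <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste(sprintf(...), collapse = "")))
}

simulate_from_config <- function(config) {
  cfg_c <- config$cohort
  cfg_g <- config$genome
  cfg_e <- config$effects
  simulate_study(
    profiles = cohort_profiles(cfg_c$n_mexican, cfg_c$n_puerto_rican,
                               cfg_c$n_mixed, cfg_c$n_other,
                               cfg_c$concentration),
    n_snps = cfg_g$n_snps, genetic_length = cfg_g$genetic_length,
    G = cfg_g$generations, duffy = isTRUE(cfg_g$duffy),
    duffy_pos_gen = cfg_g$duffy_pos_gen,
    duffy_gap_bp = cfg_g$duffy_gap_bp, duffy_beta = cfg_g$duffy_beta,
    seed = config$seed,
    n_cpgs = cfg_e$n_cpgs, n_meqtl = cfg_e$n_meqtl,
    n_theta = cfg_e$n_theta, n_env = cfg_e$n_env,
    n_signature = cfg_e$n_signature, meqtl_beta = cfg_e$meqtl_beta,
    theta_contrast = cfg_e$theta_contrast, env_shift = cfg_e$env_shift,
    noise_sd = cfg_e$noise_sd, batch_sd = cfg_e$batch_sd,
    fail_rate = cfg_e$fail_rate
  )
}

# stages 2..n on an already-simulated study; returns the results list
analyse_study <- function(study, config, subset = NULL) {
  if (!is.null(subset)) {
    study$sheet <- study$sheet[subset, , drop = FALSE]
    study$q <- study$q[subset, , drop = FALSE]
    study$cells <- study$cells[subset, , drop = FALSE]
    study$meth$values <- study$meth$values[subset, , drop = FALSE]
    study$meth$detection_p <- study$meth$detection_p[subset, , drop = FALSE]
    study$geno$dosages <- study$geno$dosages[subset, , drop = FALSE]
    study$tracts <- study$tracts[study$tracts$indiv %in%
                                   study$sheet$indiv, , drop = FALSE]
  }
  alpha <- config$thresholds$alpha
  qc <- config$qc

  meth <- filter_probes(study$meth, qc$detection_p_cut, qc$max_fail_frac)
  geno <- qc_genotypes(study$geno, study$sheet$ethnicity, qc$miss_cut,
                       qc$hwe_cut)
  log_stage("qc", "probes %d -> %d, snps %d -> %d",
            ncol(study$meth$values), ncol(meth$values),
            ncol(study$geno$dosages), ncol(geno$dosages))

  sig <- intersect(attr(study$truth, "signature_cpgs"),
                   meth$probes$probe)
  cells_est <- estimate_cell_proportions(
    meth, truth_cell_reference(study$truth, sig))$proportions
  log_stage("cells", "estimated %d cell types on %d signature probes",
            ncol(cells_est), length(sig))

  covars <- covariate_design(study$sheet, cells_est)
  M <- as_m_matrix(meth)
  eth <- factor(study$sheet$ethnicity)
  anc <- compositional_columns(study$q, ref = "EUR")

  pc <- pcoa(M, k = 10)
  pc_eth <- associate_pc(pc$coordinates, eth, covars)
  pc_anc <- associate_pc(pc$coordinates, anc,
                         cbind(covars, indicator_columns(eth, "ethnicity")))
  gpca <- genotype_pca(geno, k = 10)
  log_stage("structure", "pcoa eig1 %.1f, genotype PCA %d SNPs dropped",
            pc$eigenvalues[1], length(gpca$dropped))

  scan_eth <- ewas_ethnicity(M, eth, covars, alpha = alpha)
  scan_eth_adj <- ewas_ethnicity(M, eth, covars, ancestry = anc,
                                 alpha = alpha)
  unstable <- scan_stability(M, eth, covars, anc)
  classification <- classify_adjustment(scan_eth, scan_eth_adj, unstable)
  scan_anc <- ewas_ancestry(M, study$q, eth, covars, alpha = alpha)
  log_stage("ewas", "ethnicity hits %d, ancestry hits %d, classes %s",
            sum(scan_eth$significant), sum(scan_anc$significant),
            paste(names(attr(classification, "counts")),
                  attr(classification, "counts"), sep = "=",
                  collapse = " "))

  hits <- scan_eth$probe[scan_eth$significant]
  parts <- lapply(hits, function(pr) {
    vp <- joint_partition(M[, pr], eth, study$q, covars)
    data.frame(probe = pr, joint = vp$joint, ethnicity = vp$ethnicity,
               ancestry = vp$ancestry, ancestry_share = vp$ancestry_share,
               stable = vp$stable)
  })
  parts <- if (length(parts)) do.call(rbind, parts) else
    data.frame(probe = character(0), joint = numeric(0),
               ethnicity = numeric(0), ancestry = numeric(0),
               ancestry_share = numeric(0), stable = logical(0))

  anc_hits <- scan_anc$probe[scan_anc$significant]
  lg <- lapply(anc_hits, function(pr) {
    pos <- study$truth$cpgs$pos_gen[match(pr, study$truth$cpgs$probe)]
    dos <- local_dosage_at(study$tracts, pos)
    vp <- local_global_partition(M[, pr], dos, study$q, covars)
    data.frame(probe = pr, joint = vp$joint, local = vp$local,
               global = vp$global, local_share = vp$local_share,
               stable = vp$stable)
  })
  lg <- if (length(lg)) do.call(rbind, lg) else
    data.frame(probe = character(0), joint = numeric(0),
               local = numeric(0), global = numeric(0),
               local_share = numeric(0), stable = logical(0))
  log_stage("decomp", "partitions at %d ethnicity and %d ancestry hits",
            nrow(parts), nrow(lg))

  two_largest <- names(sort(table(study$sheet$ethnicity),
                            decreasing = TRUE))[1:2]
  in_pair <- study$sheet$ethnicity %in% two_largest
  med_pcs <- pc_eth$pc[!is.na(pc_eth$p) & pc_eth$p < 0.05]
  mediations <- lapply(med_pcs, function(pcname) {
    res <- mediate(pc$coordinates[in_pair, pcname],
                   treatment = as.numeric(
                     study$sheet$ethnicity[in_pair] == two_largest[1L]),
                   mediator = study$q[in_pair, "NAM"],
                   covariates = covars[in_pair, , drop = FALSE],
                   n_sims = config$mediation$n_sims,
                   seed = config$seed)
    list(pc = pcname, acme = res$acme, total = res$total,
         prop_mediated = res$prop_mediated,
         prop_ci = res$prop_ci, p = res$acme_p)
  })
  log_stage("mediate", "%d PCs mediated by NAM ancestry (contrast %s vs %s)",
            length(mediations), two_largest[1L], two_largest[2L])

  env_set <- intersect(attr(study$truth, "env_cpgs"), scan_eth$probe)
  p_map <- stats::setNames(scan_eth$p, scan_eth$probe)
  enr <- if (length(env_set)) {
    enrichment(hits, env_set, scan_eth$probe, p_map,
               rate0 = config$thresholds$nominal)
  }
  list(meth = meth, geno = geno, cells_est = cells_est, covars = covars,
       M = M, pcoa = pc, pc_eth = pc_eth, pc_anc = pc_anc, gpca = gpca,
       scan_eth = scan_eth, scan_eth_adj = scan_eth_adj,
       scan_anc = scan_anc, classification = classification,
       partitions = parts, local_global = lg, mediations = mediations,
       enrichment = enr)
}

median_iqr <- function(x) {
  x <- x[is.finite(x)]
  if (!length(x)) return(list(median = NA, q1 = NA, q3 = NA))
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3])
}

build_report <- function(res, config) {
  cls <- attr(res$classification, "counts")
  stable_parts <- res$partitions[res$partitions$stable &
                                   res$partitions$probe %in%
                                   res$classification$probe[
                                     res$classification$class != "unstable"],
                                 , drop = FALSE]
  list(
    seed = config$seed,
    n_samples = nrow(res$M),
    n_probes_post_qc = ncol(res$M),
    hits = list(
      ethnicity = sum(res$scan_eth$significant),
      ethnicity_threshold = attr(res$scan_eth, "threshold"),
      ancestry = sum(res$scan_anc$significant),
      ancestry_driven_by = as.list(table(
        res$scan_anc$driven_by[res$scan_anc$significant]))
    ),
    classification = as.list(cls),
    variance_partition = list(
      joint = median_iqr(stable_parts$joint),
      ethnicity = median_iqr(stable_parts$ethnicity),
      ancestry = median_iqr(stable_parts$ancestry),
      ancestry_share = median_iqr(stable_parts$ancestry_share)
    ),
    local_global = list(
      local = median_iqr(res$local_global$local),
      local_share = median_iqr(res$local_global$local_share)
    ),
    mediation = res$mediations,
    enrichment = if (!is.null(res$enrichment)) {
      unclass(res$enrichment)
    },
    pc_associations = list(
      ethnicity = res$pc_eth[, c("pc", "p")],
      ancestry = res$pc_anc[, c("pc", "p")]
    )
  )
}

#' Run the full pipeline from a configuration
#'
#' Simulates the study, runs QC, cell estimation, structure analysis, the
#' ethnicity and ancestry EWAS with classification, variance partitioning,
#' mediation and enrichment, writes all stage outputs plus a JSON report
#' under `config$output_dir`, and returns the report invisibly. Two runs
#' with the same config and seed produce byte-identical reports.
#'
#' @param config Config list ([default_config()] / [read_run_config()]).
#' @return The report list, invisibly; files under `config$output_dir`.
#' @export
run_pipeline <- function(config = default_config()) {
  out <- config$output_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  log_stage("simulate", "seed %d", config$seed)
  study <- simulate_from_config(config)
  res <- analyse_study(study, config)

  write_sample_sheet(study$sheet, file.path(out, "sample_sheet.csv"))
  write_beta_tsv(study$meth, file.path(out, "beta.tsv"))
  write_manifest_tsv(stats::setNames(
    study$truth$cpgs[, c("probe", "chrom", "pos_bp")],
    c("probe", "chrom", "pos")), file.path(out, "manifest.tsv"))
  write_dosage_tsv(study$geno, file.path(out, "dosages.tsv"))
  write_vcf(study$geno, file.path(out, "genotypes.vcf"))
  write_tracts_bed(study$tracts, file.path(out, "tracts.bed.tsv"))
  write_truth_json(study$truth, file.path(out, "truth.json"))
  write_tsv_plain(data.frame(indiv = rownames(res$pcoa$coordinates),
                             res$pcoa$coordinates),
                  file.path(out, "pcoa_scores.tsv"))
  write_tsv_plain(res$scan_eth, file.path(out, "ewas_ethnicity.tsv"))
  write_tsv_plain(res$scan_anc, file.path(out, "ewas_ancestry.tsv"))
  write_tsv_plain(res$classification, file.path(out, "classification.tsv"))
  write_tsv_plain(res$partitions, file.path(out, "partitions.tsv"))
  write_tsv_plain(res$local_global, file.path(out, "local_global.tsv"))

  report <- build_report(res, config)
  jsonlite::write_json(report, file.path(out, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  log_stage("report", "written to %s", file.path(out, "report.json"))
  invisible(report)
}

#' Re-run the association scans on a random subsample
#'
#' Mirrors a down-sampling sensitivity analysis: draws `n_target`
#' individuals without replacement (seed-controlled), reruns the analysis
#' stages, and returns the subsample report. With `n_target` equal to the
#' full cohort size the result is identical to the full run.
#'
#' @param config Config list.
#' @param n_target Subsample size.
#' @param seed Seed for the subsample draw (the simulation itself uses
#'   `config$seed`).
#' @return Report list for the subsample.
#' @export
downsample_rerun <- function(config, n_target, seed = config$seed) {
  study <- simulate_from_config(config)
  n <- nrow(study$sheet)
  if (n_target > n) {
    abort_admix("n_target exceeds cohort size", "admixmeth_invalid")
  }
  subset <- with_seed(seed, sort(sample.int(n, n_target)))
  log_stage("downsample", "n %d -> %d", n, n_target)
  res <- analyse_study(study, config, subset = subset)
  build_report(res, config)
}

#' Independent effect of recruitment site on methylation
#'
#' Per-CpG omnibus test of recruitment site adjusted for ethnicity and the
#' standard covariates — a residual-confounding check: with no simulated
#' site effect the Bonferroni hit count should be ~0.
#'
#' @param config Config list.
#' @param site_column Sample-sheet column holding the site factor.
#' @param study Optional pre-simulated `admix_study` (skips simulation).
#' @return List: `n_hits`, `threshold`, `scan` (per-CpG results).
#' @export
site_sensitivity <- function(config, site_column = "site", study = NULL) {
  if (is.null(study)) study <- simulate_from_config(config)
  site <- study$sheet[[site_column]]
  if (is.null(site)) {
    abort_admix("site column not present in the sample sheet",
                "admixmeth_invalid")
  }
  if (length(unique(site)) < 2L) {
    abort_admix("recruitment-site analysis needs at least two sites",
                "admixmeth_invalid")
  }
  meth <- filter_probes(study$meth, config$qc$detection_p_cut,
                        config$qc$max_fail_frac)
  M <- as_m_matrix(meth)
  covars <- covariate_design(study$sheet, study$cells)
  eth_block <- indicator_columns(factor(study$sheet$ethnicity),
                                 "ethnicity")
  X_red <- cbind(`(Intercept)` = rep(1, nrow(M)), covars, eth_block)
  scan <- omnibus_scan(M, X_red, indicator_columns(factor(site), "site"))
  thr <- bonferroni(config$thresholds$alpha, ncol(M))
  log_stage("site", "%d/%d Bonferroni hits at %.3g",
            sum(scan$p < thr), ncol(M), thr)
  list(n_hits = sum(scan$p < thr), threshold = thr,
       scan = cbind(probe = colnames(M), scan))
}
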