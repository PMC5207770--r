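# Synthetic admixed-cohort generator.
#
# The generator emulates a three-way admixed study population (African,
# European, Native American) of the kind studied in Latino cohorts: ethnic
# groups with distinct Dirichlet global-ancestry distributions, Markov
# local-ancestry tracts along a synthetic chromosome, genotypes drawn from
# ancestry-specific allele frequencies, and methylation M-values driven by
# cell composition, cis meQTLs, global ancestry, ethnicity-specific
# environment, batch, and Gaussian noise. Every downstream analysis stage is
# therefore testable against known truth.

#' Ancestral allele-frequency panel
#'
#' Builds a panel of SNP allele frequencies for K ancestral populations on a
#' single synthetic chromosome. Frequencies follow a Balding-Nichols model:
#' an ancestral frequency drawn uniformly, then per-population frequencies
#' from Beta distributions with differentiation parameter `fst`. Genetic and
#' physical coordinates are linked by a linear 1 cM/Mb map.
#'
#' @param n_snps Number of SNPs.
#' @param genetic_length Chromosome length in Morgans.
#' @param labels Ancestry labels (default AFR, EUR, NAM).
#' @param fst Balding-Nichols differentiation parameter.
#' @param freq_range Range of the ancestral frequency draw.
#' @param fixed_diff Optional list (`pos_gen`, `freq`) injecting a
#'   fixed-difference SNP (a Duffy-null-like variant, essentially fixed in
#'   one population and absent in the others) at a given genetic position.
#' @param seed RNG seed.
#' @return An `ancestral_panel`: list with `labels`, `freqs` (SNPs x K),
#'   `snps` (data frame: snp, pos_bp, pos_gen), `genetic_length`.
#' @export
ancestral_panel <- function(n_snps = 200, genetic_length = 2,
                            labels = c("AFR", "EUR", "NAM"), fst = 0.15,
                            freq_range = c(0.05, 0.95), fixed_diff = NULL,
                            seed = NULL) {
  stopifnot(length(labels) >= 2L, n_snps >= 1L, genetic_length > 0)
  with_seed(seed, {
    pos_gen <- sort(stats::runif(n_snps, 0, genetic_length))
    p0 <- stats::runif(n_snps, freq_range[1], freq_range[2])
    shape <- (1 - fst) / fst
    freqs <- vapply(labels, function(l) {
      stats::rbeta(n_snps, p0 * shape, (1 - p0) * shape)
    }, numeric(n_snps))
    if (!is.null(fixed_diff)) {
      stopifnot(length(fixed_diff$freq) == length(labels),
                fixed_diff$pos_gen >= 0, fixed_diff$pos_gen < genetic_length)
      pos_gen <- c(pos_gen, fixed_diff$pos_gen)
      ord <- order(pos_gen)
      freqs <- rbind(freqs, fixed_diff$freq)[ord, , drop = FALSE]
      pos_gen <- pos_gen[ord]
      n_snps <- n_snps + 1L
    }
  })
  freqs <- pmin(pmax(freqs, 0), 1)
  pos_bp <- morgans_to_bp(pos_gen)
  # enforce strictly increasing bp after rounding
  pos_bp <- pos_bp + cumsum(c(0, diff(pos_bp) <= 0))
  snps <- data.frame(snp = sprintf("rs%06d", seq_len(n_snps)),
                     pos_bp = pos_bp, pos_gen = pos_gen,
                     stringsAsFactors = FALSE)
  structure(list(labels = labels, freqs = freqs, snps = snps,
                 genetic_length = genetic_length),
            class = "ancestral_panel")
}

# linear 1 cM/Mb map: 1 Morgan = 100 cM = 100 Mb = 1e8 bp (1-based physical)
morgans_to_bp <- function(pos_gen) as.integer(round(pos_gen * 1e8)) + 1L
bp_to_morgans <- function(pos_bp) (pos_bp - 1) / 1e8

#' Ethnic-group ancestry profile
#'
#' @param label Group name.
#' @param alpha Dirichlet concentration vector over the K ancestries;
#'   `alpha / sum(alpha)` is the group's mean global ancestry.
#' @param n Number of individuals in the group.
#' @return An `ethnicity_profile` list.
#' @export
ethnicity_profile <- function(label, alpha, n) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    abort_admix("ethnicity profile requires strictly positive alpha",
                "admixmeth_invalid")
  }
  stopifnot(n >= 1L)
  structure(list(label = label, alpha = alpha, n = as.integer(n)),
            class = "ethnicity_profile")
}

#' Default ethnic-group profiles
#'
#' Two groups anchored to the observed median three-way ancestry of the two
#' largest Latino sub-groups in admixed US cohorts: Mexican (~4.3% African,
#' 40.5% European, 55.4% Native American) and Puerto Rican (~22.8% African,
#' 65.7% European, 11.2% Native American), with Dirichlet concentration 30.
#'
#' @param n_mexican,n_puerto_rican Group sizes.
#' @param concentration Total Dirichlet concentration per group.
#' @return Named list of [ethnicity_profile()] objects.
#' @export
default_profiles <- function(n_mexican = 276, n_puerto_rican = 220,
                             concentration = 30) {
  mex <- c(AFR = 0.043, EUR = 0.405, NAM = 0.554)
  pr <- c(AFR = 0.228, EUR = 0.657, NAM = 0.112)
  list(
    Mexican = ethnicity_profile("Mexican",
                                concentration * mex / sum(mex), n_mexican),
    PuertoRican = ethnicity_profile("PuertoRican",
                                    concentration * pr / sum(pr),
                                    n_puerto_rican)
  )
}

#' Four-group cohort profiles
#'
#' The full four-group structure of a diverse Latino cohort: Mexican and
#' Puerto Rican plus the smaller Mixed Latino (grandparents of more than
#' one national origin) and Other Latino groups, with median ancestries
#' intermediate between the two large groups (Mixed ~8.5/50.5/31.5,
#' Other ~12.3/48.9/32.8 AFR/EUR/NAM). The intermediate groups matter
#' statistically: they break the near-collinearity between ethnicity and
#' Native American ancestry that a two-group cohort exhibits.
#'
#' @param n_mexican,n_puerto_rican,n_mixed,n_other Group sizes.
#' @param concentration Total Dirichlet concentration per group.
#' @return Named list of [ethnicity_profile()] objects.
#' @export
cohort_profiles <- function(n_mexican = 276, n_puerto_rican = 220,
                            n_mixed = 16, n_other = 61,
                            concentration = 30) {
  mk <- function(label, v, n) {
    ethnicity_profile(label, concentration * v / sum(v), n)
  }
  list(
    Mexican = mk("Mexican", c(AFR = 0.043, EUR = 0.405, NAM = 0.554),
                 n_mexican),
    PuertoRican = mk("PuertoRican",
                     c(AFR = 0.228, EUR = 0.657, NAM = 0.112),
                     n_puerto_rican),
    MixedLatino = mk("MixedLatino",
                     c(AFR = 0.085, EUR = 0.505, NAM = 0.315), n_mixed),
    OtherLatino = mk("OtherLatino",
                     c(AFR = 0.123, EUR = 0.489, NAM = 0.328), n_other)
  )
}

#' Simulate global-ancestry proportions for a group
#'
#' @param profile An [ethnicity_profile()].
#' @param n Number of individuals (default the profile's `n`).
#' @param seed RNG seed.
#' @return `n` x K matrix of Dirichlet draws; rows sum to 1.
#' @export
simulate_global_ancestry <- function(profile, n = profile$n, seed = NULL) {
  stopifnot(inherits(profile, "ethnicity_profile"))
  with_seed(seed, {
    q <- rdirichlet(n, profile$alpha)
  })
  colnames(q) <- names(profile$alpha)
  q
}

#' Simulate local-ancestry tracts for haplotypes
#'
#' Continuous Markov model of admixture: along a chromosome of
#' `genetic_length` Morgans, ancestry switch points arrive as a Poisson
#' process with rate `G` (generations since admixture) per Morgan, and the
#' ancestry state at the chromosome start and after each switch point is
#' drawn independently from the individual's global-ancestry proportions
#' `q`. Same-state switches are retained (tracts are not merged), so the
#' stationary ancestry distribution is exactly `q`.
#'
#' @param q Global-ancestry proportions (sums to 1), named by ancestry.
#' @param genetic_length Chromosome length in Morgans.
#' @param G Generations since admixture (switch rate per Morgan); `G = 0`
#'   yields a single tract per haplotype.
#' @param n_hap Number of haplotypes to simulate.
#' @param seed RNG seed.
#' @return Data frame (hap, start, end, ancestry) on genetic coordinates,
#'   0-based half-open in Morgans; tracts tile `[0, genetic_length)` exactly.
#'   Attribute `"n_switches"` holds the raw Poisson switch-point count.
#' @export
simulate_local_tracts <- function(q, genetic_length, G, n_hap = 2L,
                                  seed = NULL) {
  if (G < 0) abort_admix("generations G must be nonnegative",
                         "admixmeth_invalid")
  if (abs(sum(q) - 1) > 1e-8 || any(q < 0)) {
    abort_admix("q must be ancestry proportions on the simplex",
                "admixmeth_invalid")
  }
  labels <- names(q)
  if (is.null(labels)) labels <- paste0("anc", seq_along(q))
  out <- with_seed(seed, {
    pieces <- vector("list", n_hap)
    total_switches <- 0L
    for (h in seq_len(n_hap)) {
      n_sw <- stats::rpois(1L, G * genetic_length)
      total_switches <- total_switches + n_sw
      bounds <- c(0, sort(stats::runif(n_sw, 0, genetic_length)),
                  genetic_length)
      states <- sample(labels, n_sw + 1L, replace = TRUE, prob = q)
      pieces[[h]] <- data.frame(
        hap = h,
        start = bounds[-length(bounds)],
        end = bounds[-1L],
        ancestry = states,
        stringsAsFactors = FALSE
      )
    }
    tr <- do.call(rbind, pieces)
    attr(tr, "n_switches") <- total_switches
    tr
  })
  attr(out, "labels") <- labels
  attr(out, "genetic_length") <- genetic_length
  out
}

# ancestry state of one haplotype's tracts at sorted query positions
tract_state_at <- function(tracts_one_hap, pos) {
  idx <- findInterval(pos, tracts_one_hap$start)
  if (any(idx < 1L) || any(pos >= max(tracts_one_hap$end))) {
    abort_admix("query position outside simulated interval",
                "admixmeth_coordinate")
  }
  tracts_one_hap$ancestry[idx]
}

#' Simulate genotypes from local-ancestry tracts
#'
#' Each haplotype's allele at a SNP is Bernoulli with the allele frequency
#' of the haplotype's local ancestry at that SNP.
#'
#' @param tracts Cohort tract table as produced by [simulate_cohort_tracts()]
#'   (columns indiv, hap, start, end, ancestry).
#' @param panel An [ancestral_panel()].
#' @param seed RNG seed.
#' @return A [genotype_matrix()] of dosages with the phased haplotype
#'   allele matrix (2n x SNPs) attached as attribute `"haplotypes"`.
#' @export
simulate_genotypes <- function(tracts, panel, seed = NULL) {
  stopifnot(inherits(panel, "ancestral_panel"))
  if (any(panel$snps$pos_gen >= attr(tracts, "genetic_length")) ||
      any(panel$snps$pos_gen < 0)) {
    abort_admix("SNP positions outside the simulated interval",
                "admixmeth_coordinate")
  }
  key <- paste(tracts$indiv, tracts$hap, sep = "\r")
  hap_keys <- unique(key)            # order of appearance: per indiv, hap 1, 2
  hap_list <- split(tracts, factor(key, levels = hap_keys))
  n_snps <- nrow(panel$snps)
  with_seed(seed, {
    hap_alleles <- t(vapply(hap_list, function(tr) {
      states <- tract_state_at(tr, panel$snps$pos_gen)
      f <- panel$freqs[cbind(seq_len(n_snps),
                             match(states, panel$labels))]
      stats::rbinom(n_snps, 1L, f)
    }, integer(n_snps)))
  })
  hap_indiv <- sub("\r.*$", "", hap_keys)
  hap_no <- sub("^.*\r", "", hap_keys)
  dos <- rowsum(hap_alleles, group = hap_indiv, reorder = FALSE)
  rownames(hap_alleles) <- paste0(hap_indiv, "_h", hap_no)
  out <- genotype_matrix(dos, panel$snps)
  attr(out, "haplotypes") <- hap_alleles
  out
}

#' Simulate tracts for a whole cohort
#'
#' One diploid genome = two independent haplotypes drawn from the
#' individual's own global-ancestry proportions.
#'
#' @param q Matrix (individuals x K) of global-ancestry proportions with
#'   ancestry colnames; rownames used as individual ids.
#' @param genetic_length Chromosome length in Morgans.
#' @param G Generations since admixture.
#' @param seed RNG seed.
#' @return Cohort tract table (indiv, hap, start, end, ancestry) with
#'   `labels` and `genetic_length` attributes; class `local_ancestry`.
#' @export
simulate_cohort_tracts <- function(q, genetic_length = 2, G = 8,
                                   seed = NULL) {
  stopifnot(is.matrix(q), !is.null(colnames(q)))
  ids <- rownames(q)
  if (is.null(ids)) ids <- sprintf("ind%04d", seq_len(nrow(q)))
  out <- with_seed(seed, {
    pieces <- lapply(seq_len(nrow(q)), function(i) {
      tr <- simulate_local_tracts(q[i, ], genetic_length, G, n_hap = 2L)
      cbind(indiv = ids[i], tr)
    })
    do.call(rbind, pieces)
  })
  rownames(out) <- NULL
  attr(out, "labels") <- colnames(q)
  attr(out, "genetic_length") <- genetic_length
  class(out) <- c("local_ancestry", "data.frame")
  out
}

#' Simulation truth record
#'
#' Per-CpG generative effects for the synthetic methylome. Effects are on
#' the M scale: `meqtl_beta` in M units per allele, `theta` in M units per
#' unit ancestry proportion, `env` in M units per group, `cell_delta` in M
#' units per unit cell proportion.
#'
#' @param cpgs Data frame (probe, chrom, pos_bp, pos_gen).
#' @param labels Ancestry labels.
#' @param groups Ethnic-group labels.
#' @param cell_types Cell-type labels.
#' @param mu Per-CpG baseline M-value.
#' @param cell_delta CpGs x cell-types effect matrix.
#' @param meqtl_snp Per-CpG SNP id (NA if none) and `meqtl_beta` effect.
#' @param meqtl_beta Per-CpG cis-meQTL effect, M per allele.
#' @param theta CpGs x K global-ancestry effect matrix.
#' @param env CpGs x groups environmental-shift matrix.
#' @param noise_sd Per-CpG residual standard deviation (> 0).
#' @param batch_sd Plate batch-effect standard deviation.
#' @return A `simulation_truth` list.
#' @export
simulation_truth <- function(cpgs, labels, groups, cell_types, mu,
                             cell_delta, meqtl_snp, meqtl_beta, theta, env,
                             noise_sd, batch_sd = 0) {
  n <- nrow(cpgs)
  stopifnot(length(mu) == n, nrow(cell_delta) == n,
            length(meqtl_snp) == n, length(meqtl_beta) == n,
            nrow(theta) == n, ncol(theta) == length(labels),
            nrow(env) == n, ncol(env) == length(groups),
            length(noise_sd) == n)
  if (any(noise_sd <= 0)) {
    abort_admix("noise sd must be strictly positive", "admixmeth_invalid")
  }
  structure(list(cpgs = cpgs, labels = labels, groups = groups,
                 cell_types = cell_types, mu = mu, cell_delta = cell_delta,
                 meqtl_snp = meqtl_snp, meqtl_beta = meqtl_beta,
                 theta = theta, env = env, noise_sd = noise_sd,
                 batch_sd = batch_sd),
            class = "simulation_truth")
}

#' Build a default effect architecture
#'
#' Assigns disjoint sets of CpGs a cis-meQTL effect, a global-ancestry
#' effect, or an ethnicity-specific environmental shift; a further set
#' carries strong cell-type signature effects so reference-based
#' deconvolution has informative probes. Ancestry effects are parameterized
#' by the ethnic-group M-value contrast they induce: theta on the
#' `anchor_ancestry` component equals `theta_contrast` divided by the
#' difference in that component's mean between the first two groups, so
#' mediated and environmental effects are on the same scale.
#'
#' @param panel An [ancestral_panel()].
#' @param profiles Ethnic-group profiles (list of [ethnicity_profile()]).
#' @param n_cpgs Number of CpGs.
#' @param n_meqtl,n_theta,n_env,n_signature Architecture set sizes.
#' @param meqtl_beta Cis effect in M per allele.
#' @param theta_contrast Group contrast (M units) induced by the ancestry
#'   effect; `env_shift` the direct environmental group shift (M units).
#' @param env_shift Environmental shift, M units, applied to the first group.
#' @param anchor_ancestry Ancestry component carrying theta effects.
#' @param noise_sd Residual sd (M units).
#' @param cell_sd Background cell-effect sd; signature probes use
#'   `signature_sd`.
#' @param signature_sd Cell-signature effect sd.
#' @param batch_sd Plate batch sd.
#' @param cell_types Cell-type labels.
#' @param fail_rate Probe detection-failure rate.
#' @param seed RNG seed.
#' @return A `simulation_truth` with attributes `meqtl_cpgs`, `theta_cpgs`,
#'   `env_cpgs`, `signature_cpgs`, `fail_rate`.
#' @export
default_truth <- function(panel, profiles, n_cpgs = 500, n_meqtl = 40,
                          n_theta = 80, n_env = 80, n_signature = 60,
                          meqtl_beta = 1.35, theta_contrast = 0.5,
                          env_shift = 0.5, anchor_ancestry = "NAM",
                          noise_sd = 0.45, cell_sd = 0.2, signature_sd = 2,
                          batch_sd = 0, cell_types = c("Granulocyte",
                                                       "Lymphocyte",
                                                       "Monocyte"),
                          fail_rate = 0.002, seed = NULL) {
  stopifnot(inherits(panel, "ancestral_panel"),
            n_meqtl + n_theta + n_env + n_signature <= n_cpgs)
  labels <- panel$labels
  groups <- vapply(profiles, `[[`, character(1), "label")
  with_seed(seed, {
    pos_gen <- sort(stats::runif(n_cpgs, 0, panel$genetic_length))
    cpgs <- data.frame(probe = sprintf("cg%07d", seq_len(n_cpgs)),
                       chrom = "chr1", pos_bp = morgans_to_bp(pos_gen),
                       pos_gen = pos_gen, stringsAsFactors = FALSE)
    cpgs$pos_bp <- cpgs$pos_bp + cumsum(c(0, diff(cpgs$pos_bp) <= 0))
    idx <- sample.int(n_cpgs)
    sets <- split(idx[seq_len(n_meqtl + n_theta + n_env + n_signature)],
                  rep(c("meqtl", "theta", "env", "signature"),
                      c(n_meqtl, n_theta, n_env, n_signature)))
    mu <- stats::runif(n_cpgs, -3, 3)
    cell_delta <- matrix(stats::rnorm(n_cpgs * length(cell_types), 0,
                                      cell_sd),
                         n_cpgs, length(cell_types),
                         dimnames = list(NULL, cell_types))
    cell_delta[sets$signature, ] <-
      stats::rnorm(length(sets$signature) * length(cell_types), 0,
                   signature_sd)
    meqtl_snp <- rep(NA_character_, n_cpgs)
    mbeta <- numeric(n_cpgs)
    if (n_meqtl > 0) {
      # each meQTL CpG is driven by its nearest SNP (cis by construction)
      nearest <- vapply(sets$meqtl, function(j) {
        which.min(abs(panel$snps$pos_gen - cpgs$pos_gen[j]))
      }, integer(1))
      meqtl_snp[sets$meqtl] <- panel$snps$snp[nearest]
      mbeta[sets$meqtl] <- meqtl_beta
    }
    theta <- matrix(0, n_cpgs, length(labels),
                    dimnames = list(NULL, labels))
    if (n_theta > 0) {
      dq <- profiles[[1]]$alpha / sum(profiles[[1]]$alpha) -
        profiles[[2]]$alpha / sum(profiles[[2]]$alpha)
      theta[sets$theta, anchor_ancestry] <-
        theta_contrast / dq[anchor_ancestry]
    }
    env <- matrix(0, n_cpgs, length(groups),
                  dimnames = list(NULL, groups))
    if (n_env > 0) env[sets$env, 1L] <- env_shift
  })
  tr <- simulation_truth(cpgs, labels, groups, cell_types, mu, cell_delta,
                         meqtl_snp, mbeta, theta, env,
                         noise_sd = rep(noise_sd, n_cpgs),
                         batch_sd = batch_sd)
  attr(tr, "meqtl_cpgs") <- cpgs$probe[sort(sets$meqtl)]
  attr(tr, "theta_cpgs") <- cpgs$probe[sort(sets$theta)]
  attr(tr, "env_cpgs") <- cpgs$probe[sort(sets$env)]
  attr(tr, "signature_cpgs") <- cpgs$probe[sort(sets$signature)]
  attr(tr, "fail_rate") <- fail_rate
  tr
}

#' Simulate a methylation matrix from the generative model
#'
#' M-values are `mu + cells' delta + g * beta_meqtl + q' theta + env(group)
#' + batch(plate) + Normal(0, sd)`, returned on the beta scale
#' (`2^M / (2^M + 1)`) with detection p-values: probes drawn as failures (at
#' the truth's `fail_rate`) receive Uniform(0,1) detection p in every
#' sample, all other entries 0.
#'
#' @param truth A [simulation_truth()].
#' @param sheet Sample sheet data frame with columns `indiv`, `ethnicity`,
#'   `plate`.
#' @param q Individuals x K global-ancestry matrix.
#' @param cells Individuals x cell-types proportion matrix.
#' @param geno A [genotype_matrix()] covering all referenced meQTL SNPs.
#' @param seed RNG seed.
#' @return A [meth_matrix()] on the beta scale with detection p-values.
#' @export
simulate_methylation <- function(truth, sheet, q, cells, geno,
                                 seed = NULL) {
  stopifnot(inherits(truth, "simulation_truth"),
            inherits(geno, "genotype_matrix"))
  n <- nrow(sheet)
  n_cpgs <- nrow(truth$cpgs)
  used <- stats::na.omit(unique(truth$meqtl_snp))
  if (!all(used %in% geno$snps$snp)) {
    abort_admix("truth references SNPs absent from the genotype matrix",
                "admixmeth_config")
  }
  grp_idx <- match(sheet$ethnicity, truth$groups)
  if (anyNA(grp_idx)) {
    abort_admix("sample sheet ethnicity not covered by truth groups",
                "admixmeth_config")
  }
  M <- matrix(rep(truth$mu, each = n), n, n_cpgs)
  M <- M + cells[, truth$cell_types, drop = FALSE] %*% t(truth$cell_delta)
  M <- M + q[, truth$labels, drop = FALSE] %*% t(truth$theta)
  M <- M + t(truth$env)[grp_idx, , drop = FALSE]
  has_meqtl <- which(!is.na(truth$meqtl_snp))
  if (length(has_meqtl)) {
    g <- geno$dosages[, truth$meqtl_snp[has_meqtl], drop = FALSE]
    M[, has_meqtl] <- M[, has_meqtl] +
      g * rep(truth$meqtl_beta[has_meqtl], each = n)
  }
  with_seed(seed, {
    if (truth$batch_sd > 0) {
      plate <- droplevels(as.factor(sheet$plate))
      plate_eff <- matrix(stats::rnorm(nlevels(plate) * n_cpgs, 0,
                                       truth$batch_sd),
                          nlevels(plate), n_cpgs)
      M <- M + plate_eff[as.integer(plate), , drop = FALSE]
    }
    M <- M + matrix(stats::rnorm(n * n_cpgs, 0,
                                 rep(truth$noise_sd, each = n)),
                    n, n_cpgs)
    fail_rate <- attr(truth, "fail_rate")
    if (is.null(fail_rate)) fail_rate <- 0
    failed <- stats::runif(n_cpgs) < fail_rate
    det_p <- matrix(0, n, n_cpgs)
    if (any(failed)) {
      det_p[, failed] <- stats::runif(n * sum(failed))
    }
  })
  beta <- m_to_beta(M)
  rownames(beta) <- sheet$indiv
  colnames(beta) <- truth$cpgs$probe
  meth_matrix(beta, truth$cpgs[, c("probe", "chrom", "pos_bp")] |>
                stats::setNames(c("probe", "chrom", "pos")),
              scale = "beta", detection_p = det_p)
}

#' True cell-reference profiles implied by a simulation truth
#'
#' The pure cell-type M-value profile at probe j for cell k is
#' `mu_j + cell_delta_jk`; restricted to the signature probes this is the
#' reference matrix a deconvolution would use.
#'
#' @param truth A [simulation_truth()] from [default_truth()].
#' @param probes Probe ids to include (default the signature set).
#' @return A [cell_reference()].
#' @export
truth_cell_reference <- function(truth,
                                 probes = attr(truth, "signature_cpgs")) {
  j <- match(probes, truth$cpgs$probe)
  stopifnot(!anyNA(j))
  prof <- t(sweep(truth$cell_delta[j, , drop = FALSE], 1L, truth$mu[j], "+"))
  rownames(prof) <- truth$cell_types
  colnames(prof) <- probes
  cell_reference(prof)
}

#' Simulate a complete synthetic study
#'
#' End-to-end generator: ethnic groups with Dirichlet global ancestry,
#' Markov local-ancestry tracts, genotypes from ancestry-specific allele
#' frequencies, cell proportions, demographic covariates and batch layout,
#' and a methylation matrix from the generative model. Optionally injects a
#' Duffy-null-like locus: a SNP fixed in the African panel and absent
#' elsewhere, driving methylation at a CpG a configurable distance away.
#'
#' @param profiles Ethnic-group profiles, default [default_profiles()].
#' @param panel Optional pre-built [ancestral_panel()]; by default one is
#'   drawn using `n_snps`, `genetic_length` and the seed.
#' @param truth Optional pre-built [simulation_truth()]; by default
#'   [default_truth()] with `...` passed through.
#' @param n_snps,genetic_length,G Panel size, chromosome length (Morgans)
#'   and generations since admixture.
#' @param duffy If `TRUE`, add a fixed-difference SNP (AFR frequency 1,
#'   others 0) and a target CpG `duffy_gap_bp` away with cis effect
#'   `duffy_beta` M-units per allele.
#' @param duffy_pos_gen Genetic position (Morgans) of the Duffy-like SNP.
#' @param duffy_gap_bp Physical distance from SNP to its CpG.
#' @param duffy_beta Cis effect at the Duffy-like CpG, M per allele.
#' @param cell_concentration Dirichlet concentration for individual cell
#'   proportions around the whole-blood mean (granulocytes 51%, lymphocytes
#'   42%, monocytes 7%).
#' @param seed RNG seed; all stages derive their streams from it.
#' @param ... Passed to [default_truth()] (effect sizes, set sizes, noise).
#' @return An `admix_study` list: `sheet`, `q` (true global ancestry),
#'   `cells` (true proportions), `tracts`, `geno`, `meth` (beta scale),
#'   `truth`, `panel`, `profiles`.
#' @export
simulate_study <- function(profiles = default_profiles(), panel = NULL,
                           truth = NULL, n_snps = 200, genetic_length = 2,
                           G = 8, duffy = FALSE, duffy_pos_gen = 0.5,
                           duffy_gap_bp = 212, duffy_beta = 1.35,
                           cell_concentration = 120, seed = NULL, ...) {
  with_seed(seed, {
    if (is.null(panel)) {
      fixed <- if (duffy) {
        list(pos_gen = duffy_pos_gen,
             freq = as.numeric(c("AFR", "EUR", "NAM") == "AFR"))
      }
      panel <- ancestral_panel(n_snps = n_snps,
                               genetic_length = genetic_length,
                               fixed_diff = fixed)
    }
    if (is.null(truth)) {
      truth <- default_truth(panel, profiles, ...)
      if (duffy) {
        # re-point one CpG at the fixed-difference SNP, duffy_gap_bp away
        j_snp <- which.min(abs(panel$snps$pos_gen - duffy_pos_gen))
        duffy_snp <- panel$snps$snp[j_snp]
        j_cpg <- which.min(abs(truth$cpgs$pos_gen - duffy_pos_gen))
        truth$cpgs$pos_bp[j_cpg] <- panel$snps$pos_bp[j_snp] + duffy_gap_bp
        truth$cpgs$pos_gen[j_cpg] <- bp_to_morgans(truth$cpgs$pos_bp[j_cpg])
        truth$meqtl_snp[j_cpg] <- duffy_snp
        truth$meqtl_beta[j_cpg] <- duffy_beta
        truth$theta[j_cpg, ] <- 0
        truth$env[j_cpg, ] <- 0
        ord <- order(truth$cpgs$pos_gen)
        for (f in c("mu", "meqtl_snp", "meqtl_beta", "noise_sd")) {
          truth[[f]] <- truth[[f]][ord]
        }
        for (f in c("cpgs", "cell_delta", "theta", "env")) {
          truth[[f]] <- truth[[f]][ord, , drop = FALSE]
        }
        attr(truth, "duffy_snp") <- duffy_snp
        attr(truth, "duffy_cpg") <- truth$cpgs$probe[
          match(duffy_snp, truth$meqtl_snp)]
      }
    }
    groups <- vapply(profiles, `[[`, character(1), "label")
    n_per <- vapply(profiles, `[[`, integer(1), "n")
    n <- sum(n_per)
    ids <- sprintf("ind%04d", seq_len(n))
    ethnicity <- rep(groups, n_per)
    q <- do.call(rbind, lapply(profiles, simulate_global_ancestry))
    rownames(q) <- ids
    # demographics loosely matched to a pediatric asthma case-control cohort
    case_rate <- stats::setNames(rep(0.55, length(groups)), groups)
    case_rate[groups[1]] <- 0.45
    if (length(groups) >= 2) case_rate[groups[2]] <- 0.67
    sheet <- data.frame(
      indiv = ids,
      ethnicity = ethnicity,
      age = round(pmin(pmax(stats::rnorm(n, 12, 2.5), 8), 21), 1),
      sex = sample(c("F", "M"), n, replace = TRUE),
      case = stats::rbinom(n, 1L, case_rate[ethnicity]),
      plate = sample(sprintf("plate%02d", 1:6), n, replace = TRUE),
      position = sample(sprintf("R%02d", 1:12), n, replace = TRUE),
      site = NA_character_,
      stringsAsFactors = FALSE
    )
    site_probs <- list(
      c(Chicago = 0.507, NewYork = 0.065, SanFrancisco = 0.283,
        Houston = 0.145),
      c(PuertoRico = 0.877, Chicago = 0.068, NewYork = 0.045,
        Houston = 0.01),
      c(Chicago = 0.56, SanFrancisco = 0.31, Houston = 0.13),
      c(NewYork = 0.38, SanFrancisco = 0.38, Chicago = 0.16,
        Houston = 0.08)
    )
    for (gi in seq_along(groups)) {
      pr <- site_probs[[min(gi, length(site_probs))]]
      in_g <- sheet$ethnicity == groups[gi]
      sheet$site[in_g] <- sample(names(pr), sum(in_g), replace = TRUE,
                                 prob = pr)
    }
    cells <- rdirichlet(n, cell_concentration * c(0.51, 0.42, 0.07))
    colnames(cells) <- truth$cell_types
    rownames(cells) <- ids
    tracts <- simulate_cohort_tracts(q, genetic_length, G)
    geno <- simulate_genotypes(tracts, panel)
    meth <- simulate_methylation(truth, sheet, q, cells, geno)
  })
  structure(list(sheet = sheet, q = q, cells = cells, tracts = tracts,
                 geno = geno, meth = meth, truth = truth, panel = panel,
                 profiles = profiles),
            class = "admix_study")
}

#' @export
print.admix_study <- function(x, ...) {
  cat(sprintf(
    "admix_study: %d individuals (%s), %d SNPs, %d CpGs, %d-way admixture\n",
    nrow(x$sheet),
    paste(sprintf("%s n=%d", names(table(x$sheet$ethnicity)),
                  table(x$sheet$ethnicity)), collapse = ", "),
    nrow(x$geno$snps), nrow(x$truth$cpgs), length(x$panel$labels)))
  invisible(x)
}
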