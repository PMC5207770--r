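# Generator: Dirichlet ancestry, Markov tracts, genotypes, methylation.

test_that("global ancestry draws live on the simplex with the right means", {
  q <- simulate_global_ancestry(ethnicity_profile("u", c(1, 1, 1), 3),
                                seed = 1)
  expect_equal(rowSums(q), rep(1, 3))
  expect_true(all(q >= 0))

  # Dirichlet moment oracle: mean_k = alpha_k / sum(alpha),
  # var_k = mean_k (1 - mean_k) / (sum(alpha) + 1)
  alpha <- 30 * c(AFR = 4.3, EUR = 40.5, NAM = 55.4) / 100.2
  prof <- ethnicity_profile("mex", alpha, 5000)
  q <- simulate_global_ancestry(prof, seed = 2)
  m <- alpha / sum(alpha)
  mc_se <- sqrt(m * (1 - m) / (sum(alpha) + 1) / 5000)
  expect_true(all(abs(colMeans(q) - m) < 2 * mc_se))

  # default Puerto Rican profile mean ~ (0.228, 0.657, 0.112) AFR/EUR/NAM
  pr <- default_profiles()$PuertoRican
  q <- simulate_global_ancestry(pr, n = 20000, seed = 3)
  expect_equal(unname(colMeans(q)), c(0.228, 0.657, 0.112),
               tolerance = 0.02)

  expect_error(ethnicity_profile("bad", c(1, -1, 1), 10), "positive")
})

test_that("tract process has Poisson switch counts and stationary q", {
  q <- c(AFR = 0.3, EUR = 0.5, NAM = 0.2)
  # G = 0: exactly one tract per haplotype
  tr0 <- simulate_local_tracts(q, genetic_length = 3, G = 0, n_hap = 4,
                               seed = 1)
  expect_equal(nrow(tr0), 4L)
  expect_equal(attr(tr0, "n_switches"), 0L)

  # Poisson mean oracle: E[switches] = G * L per haplotype
  n_hap <- 10000
  tr <- simulate_local_tracts(q, genetic_length = 3, G = 8, n_hap = n_hap,
                              seed = 2)
  mean_sw <- attr(tr, "n_switches") / n_hap
  mc_se <- sqrt(24 / n_hap)    # Poisson variance = mean
  expect_lt(abs(mean_sw - 24), 2 * mc_se)

  # stationarity: genome-wide dosage averages to q over many haplotypes
  len_by_anc <- tapply(tr$end - tr$start, tr$ancestry, sum)
  prop <- len_by_anc[names(q)] / (3 * n_hap)
  expect_true(all(abs(prop - q) < 0.01))

  expect_error(simulate_local_tracts(q, 2, G = -1), "nonnegative")
  expect_error(simulate_local_tracts(c(0.5, 0.2), 2, G = 1), "simplex")
})

test_that("mean tract length approximates 1/G Morgans for long chromosomes", {
  q <- c(A = 0.5, B = 0.5)
  tr <- simulate_local_tracts(q, genetic_length = 50, G = 8, n_hap = 200,
                              seed = 3)
  # renewal-process mean: interior segment lengths ~ Exp(G), mean 1/G
  expect_equal(mean(tr$end - tr$start), 1 / 8, tolerance = 0.05)
})

test_that("genotypes follow local-ancestry allele frequencies", {
  prof <- default_profiles(40, 40)
  q <- rbind(simulate_global_ancestry(prof$Mexican, seed = 1),
             simulate_global_ancestry(prof$PuertoRican, seed = 2))
  rownames(q) <- sprintf("i%03d", seq_len(nrow(q)))
  tracts <- simulate_cohort_tracts(q, genetic_length = 2, G = 8, seed = 3)

  # freq = 1 everywhere -> dosage 2 everywhere
  pan1 <- ancestral_panel(n_snps = 5, seed = 4)
  pan1$freqs[] <- 1
  g1 <- simulate_genotypes(tracts, pan1, seed = 5)
  expect_true(all(g1$dosages == 2))

  # fixed-difference SNP: dosage equals African local-ancestry dosage
  pan2 <- ancestral_panel(n_snps = 5, seed = 6)
  pan2$freqs[3, ] <- c(1, 0, 0)   # AFR = 1, EUR = NAM = 0
  g2 <- simulate_genotypes(tracts, pan2, seed = 7)
  afr_dos <- local_dosage_at(tracts, pan2$snps$pos_gen[3])[, "AFR"]
  expect_equal(unname(g2$dosages[, 3]), unname(afr_dos))

  # E[dosage] = sum_k dose_k f_k: slope of dosage on AFR dosage is
  # f_AFR - f_other = 0.8 when freqs are (0.9, 0.1, 0.1)
  pan3 <- ancestral_panel(n_snps = 5, seed = 8)
  pan3$freqs[2, ] <- c(0.9, 0.1, 0.1)
  g3 <- simulate_genotypes(tracts, pan3, seed = 9)
  afr2 <- local_dosage_at(tracts, pan3$snps$pos_gen[2])[, "AFR"]
  fit <- stats::lm(g3$dosages[, 2] ~ afr2)
  expect_lt(abs(stats::coef(fit)[["afr2"]] - 0.8),
            2 * summary(fit)$coefficients["afr2", "Std. Error"])

  # SNP outside the simulated interval is a coordinate error
  pan_bad <- ancestral_panel(n_snps = 3, genetic_length = 5, seed = 10)
  expect_error(simulate_genotypes(tracts, pan_bad), "interval")
})

test_that("methylation generative model has the stated moments", {
  st <- tiny_study(seed = 11)
  pan <- st$panel
  # all effects zero, sd = 0.1: per-CpG sample variance ~ 0.01
  tr <- st$truth
  tr$cell_delta[] <- 0; tr$theta[] <- 0; tr$env[] <- 0
  tr$meqtl_beta[] <- 0; tr$noise_sd[] <- 0.1; tr$batch_sd <- 0
  meth <- simulate_methylation(tr, st$sheet, st$q, st$cells, st$geno,
                               seed = 12)
  v <- apply(beta_to_m(meth$values), 2L, var)
  n <- nrow(st$sheet)
  # chi-square variance oracle: Var(s^2) = 2 sigma^4 / (n - 1)
  mc_se <- sqrt(2 * 0.01^2 / (n - 1))
  expect_lt(abs(mean(v) - 0.01), 2 * mc_se)   # mean over CpGs is tighter

  # env shift of +0.5 for group 1, everything else zero: OLS recovers it
  tr$noise_sd[] <- 0.45
  tr$env[, 1] <- 0.5
  meth2 <- simulate_methylation(tr, st$sheet, st$q, st$cells, st$geno,
                                seed = 13)
  M2 <- beta_to_m(meth2$values)
  grp <- as.numeric(st$sheet$ethnicity == st$truth$groups[1])
  fits <- lapply(seq(1, 80, by = 8), function(j) {
    summary(stats::lm(M2[, j] ~ grp))$coefficients["grp", 1:2]
  })
  est <- vapply(fits, `[[`, numeric(1), 1L)
  se <- vapply(fits, `[[`, numeric(1), 2L)
  expect_lt(abs(mean(est) - 0.5), 2 * sqrt(mean(se^2) / length(se)))

  # referencing an absent SNP is a config error
  tr_bad <- st$truth
  tr_bad$meqtl_snp[1] <- "rs_not_there"
  tr_bad$meqtl_beta[1] <- 1
  expect_error(simulate_methylation(tr_bad, st$sheet, st$q, st$cells,
                                    st$geno), "absent")
})

test_that("simulation is bit-identical under a fixed seed", {
  a <- tiny_study(seed = 99)
  b <- tiny_study(seed = 99)
  expect_identical(a$meth$values, b$meth$values)
  expect_identical(a$geno$dosages, b$geno$dosages)
  expect_identical(a$tracts, b$tracts)
  c <- tiny_study(seed = 100)
  expect_false(identical(a$meth$values, c$meth$values))
})

test_that("global ancestry recovered from tracts matches the draw", {
  # round trip: global_from_local o simulate_cohort_tracts ~ q
  prof <- default_profiles(150, 120)
  q <- rbind(simulate_global_ancestry(prof$Mexican, seed = 20),
             simulate_global_ancestry(prof$PuertoRican, seed = 21))
  rownames(q) <- sprintf("i%03d", seq_len(nrow(q)))
  tracts <- simulate_cohort_tracts(q, genetic_length = 2, G = 8, seed = 22)
  q_hat <- global_from_local(tracts)
  expect_equal(rowSums(q_hat), rep(1, nrow(q)), ignore_attr = TRUE)
  rms <- sqrt(mean((q_hat - q[rownames(q_hat), colnames(q_hat)])^2))
  expect_lt(rms, 0.2)   # few switches at 2 Morgans: wide MC error per person
  expect_lt(max(abs(colMeans(q_hat) - colMeans(q))), 0.02)
})
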