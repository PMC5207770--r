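# Data model: beta/M conversion, probe and genotype QC, deconvolution.

test_that("beta/M conversion is the exact base-2 logit and its inverse", {
  expect_equal(beta_to_m(0.5), 0)
  expect_equal(beta_to_m(0.8), 2)           # log2(4)
  expect_equal(m_to_beta(beta_to_m(0.3)), 0.3)
  # strictly increasing, maps onto (0,1)
  b <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(beta_to_m(b)) > 0))
  expect_true(all(m_to_beta(c(-50, -1, 0, 1, 50)) > 0 &
                    m_to_beta(c(-50, -1, 0, 1, 50)) < 1))
  expect_warning(beta_to_m(c(0, 0.5)), "clipped")
  expect_error(beta_to_m(-0.1), "lie in")
})

test_that("detection-p filter drops exactly the failing probes", {
  vals <- matrix(0.5, 4, 5,
                 dimnames = list(NULL, paste0("cg", 1:5)))
  probes <- data.frame(probe = paste0("cg", 1:5), chrom = "chr1",
                       pos = 1:5 * 100L)
  dp0 <- matrix(0, 4, 5)
  m0 <- meth_matrix(vals, probes, "beta", dp0)
  expect_equal(filter_probes(m0)$probes$probe, probes$probe)

  # one probe failing in every sample: exactly that probe removed
  dp1 <- dp0; dp1[, 3] <- 0.9
  m1 <- meth_matrix(vals, probes, "beta", dp1)
  f1 <- filter_probes(m1)
  expect_equal(attr(f1, "removed"), "cg3")
  expect_equal(f1$probes$probe, paste0("cg", c(1, 2, 4, 5)))

  # enumerated toy: p_cut 0.01, max_fail_frac 0.01 -> any failure removes
  dp2 <- dp0
  dp2[1, 1] <- 0.02   # 1/4 samples fail > 0.01
  dp2[2, 4] <- 0.005  # below p_cut: not a failure
  m2 <- meth_matrix(vals, probes, "beta", dp2)
  surv <- vapply(1:5, function(j) mean(dp2[, j] > 0.01) <= 0.01,
                 logical(1))  # exhaustive row check
  expect_equal(filter_probes(m2)$probes$probe, probes$probe[surv])
  expect_equal(sum(surv), 4L)

  # idempotence
  expect_equal(filter_probes(f1)$probes, f1$probes)

  dp_all <- dp0 + 1
  expect_error(filter_probes(meth_matrix(vals, probes, "beta", dp_all)),
               "all probes removed")
})

test_that("HWE exact p matches full enumeration and edge cases", {
  # balanced counts: the most probable configuration, p ~ 1
  expect_gt(hwe_exact_p(25, 50, 25), 0.95)
  # monomorphic: p = 1
  expect_equal(hwe_exact_p(50, 0, 0), 1)
  # against the independent enumeration oracle on a grid of counts
  cases <- list(c(25, 50, 25), c(60, 25, 15), c(10, 55, 35), c(88, 10, 2),
                c(5, 0, 5), c(40, 20, 40), c(97, 2, 1))
  for (cs in cases) {
    expect_equal(hwe_exact_p(cs[1], cs[2], cs[3]),
                 hwe_oracle(cs[1], cs[2], cs[3]), tolerance = 1e-12)
  }
  # cross-check the extreme case against binomial intuition: all hets
  expect_lt(hwe_exact_p(0, 100, 0), 1e-6)
})

test_that("genotype QC removes by missingness then within-group HWE", {
  set.seed(7)
  n <- 120
  missy <- rbinom(n, 2, 0.4)
  missy[1:8] <- NA                        # 6.7% missing > 5% cut
  dos <- cbind(
    ok = rbinom(n, 2, 0.4),
    missy = missy,
    hwe_bad = rep(c(0, 2), 60)            # het deficiency within each group
  )
  snps <- data.frame(snp = colnames(dos), pos_bp = c(100L, 200L, 300L),
                     pos_gen = c(1e-6, 2e-6, 3e-6))
  g <- genotype_matrix(dos, snps)
  grp <- rep(c("a", "b"), each = 60)
  out <- qc_genotypes(g, grp)
  log <- attr(out, "removal_log")
  expect_true("missy" %in% log$snp[log$reason == "missingness"])
  expect_true("hwe_bad" %in% log$snp[log$reason == "hwe"])
  expect_equal(out$snps$snp, "ok")

  # QC is idempotent
  out2 <- qc_genotypes(out, grp)
  expect_equal(out2$snps, out$snps)

  # tiny group skipped with warning
  expect_warning(qc_genotypes(g, c(rep("big", 117), rep("tiny", 3))),
                 "tiny")
})

test_that("constrained deconvolution is exact on noiseless mixtures", {
  set.seed(11)
  k <- 3; p <- 50
  prof <- matrix(rnorm(k * p, 0, 2), k, p,
                 dimnames = list(c("Gran", "Lymph", "Mono"),
                                 paste0("cg", seq_len(p))))
  ref <- cell_reference(prof)
  probes <- data.frame(probe = paste0("cg", seq_len(p)), chrom = "chr1",
                       pos = seq_len(p) * 50L)

  mk_meth <- function(x) {
    meth_matrix(matrix(x, nrow = nrow(x), dimnames = list(NULL,
                                                          probes$probe)),
                probes, "M")
  }
  # pure profile k -> indicator vector
  est <- estimate_cell_proportions(mk_meth(prof["Lymph", , drop = FALSE] *
                                             1), ref)
  expect_equal(unname(est$proportions[1, ]), c(0, 1, 0), tolerance = 1e-8)
  expect_lt(est$residual_norm, 1e-8)

  # 50/50 mix, noiseless -> (0.5, 0.5, 0) exactly
  mix <- matrix(0.5 * prof["Gran", ] + 0.5 * prof["Mono", ], nrow = 1)
  est2 <- estimate_cell_proportions(mk_meth(mix), ref)
  expect_equal(unname(est2$proportions[1, ]), c(0.5, 0, 0.5),
               tolerance = 1e-8)

  # noisy mixtures: mean absolute error < 0.02 at 200 probes
  p2 <- 200
  prof2 <- matrix(rnorm(k * p2, 0, 2), k, p2,
                  dimnames = list(rownames(prof), paste0("cg", 1:p2)))
  probes2 <- data.frame(probe = paste0("cg", 1:p2), chrom = "chr1",
                        pos = 1:p2 * 50L)
  true_p <- rdirichlet(40, c(5, 4, 2))
  X <- true_p %*% prof2 + matrix(rnorm(40 * p2, 0, 0.05), 40)
  colnames(X) <- probes2$probe
  est3 <- estimate_cell_proportions(meth_matrix(X, probes2, "M"),
                                    cell_reference(prof2))
  expect_lt(mean(abs(est3$proportions - true_p)), 0.02)

  # estimates invariant to probe reordering
  ord <- sample(p2)
  est4 <- estimate_cell_proportions(
    meth_matrix(X[, ord], probes2[ord, ], "M"), cell_reference(prof2))
  expect_equal(est4$proportions, est3$proportions)

  # rank-deficient reference errors, naming the collinear types
  prof_bad <- prof
  prof_bad["Mono", ] <- 2 * prof_bad["Gran", ]
  expect_error(estimate_cell_proportions(mk_meth(mix),
                                         cell_reference(prof_bad)),
               "collinear")
})
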