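# Association machinery: OLS, nested ANOVA, scans, stability,
# non-linearity, thresholds, enrichment, admixture mapping, cis scans.

test_that("fit_ols matches hand arithmetic and is permutation-invariant", {
  # exact linear relationship: RSS = 0, slope exact
  x <- c(1, 2, 3, 4, 5)
  y_exact <- 2 + 3 * x
  f <- fit_ols(y_exact, cbind(`(Intercept)` = 1, x = x))
  expect_equal(unname(f$coefficients), c(2, 3))
  expect_lt(f$rss, 1e-20)

  # hand-listed 5 points: slope = Sxy / Sxx
  y <- c(2.1, 3.9, 6.2, 7.8, 10.1)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  f2 <- fit_ols(y, cbind(`(Intercept)` = 1, x = x))
  expect_equal(unname(f2$coefficients[["x"]]), sxy / sxx)

  # permuting rows gives an identical fit
  prm <- c(3, 1, 5, 2, 4)
  f3 <- fit_ols(y[prm], cbind(`(Intercept)` = 1, x = x[prm]))
  expect_equal(f3$coefficients, f2$coefficients)
  expect_equal(f3$rss, f2$rss)

  # rank deficiency names the dependent column
  expect_error(fit_ols(y, cbind(`(Intercept)` = 1, a = x, b = 2 * x)),
               "rank deficient.*\\b(a|b)\\b")
})

test_that("nested ANOVA equals t^2 for one column and matches stats::anova", {
  set.seed(23)
  n <- 50
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 1 + 0.5 * x1 + 0.3 * x2 + rnorm(n)
  X_red <- cbind(`(Intercept)` = 1, x1 = x1)
  X_full <- cbind(X_red, x2 = x2)
  full <- fit_ols(y, X_full); red <- fit_ols(y, X_red)
  nt <- nested_anova(full, red)
  # F = t^2 for a single added column
  tstat <- full$coefficients[["x2"]] / full$se[["x2"]]
  expect_equal(nt$F, tstat^2, tolerance = 1e-10)
  # independent oracle: stats::anova on lm fits
  a <- anova(lm(y ~ x1), lm(y ~ x1 + x2))
  expect_equal(nt$F, a$F[2], tolerance = 1e-10)
  expect_equal(nt$p, a$`Pr(>F)`[2], tolerance = 1e-10)
  # full = reduced: F = 0, p = 1
  same <- nested_anova(full, full)
  expect_equal(same$F, 0); expect_equal(same$p, 1)
  # non-nested designs rejected
  other <- fit_ols(y, cbind(`(Intercept)` = 1, z = rnorm(n)))
  expect_error(nested_anova(other, red), "not nested")
})

test_that("omnibus p-values are uniform under the null", {
  set.seed(29)
  n <- 80
  grp <- factor(rep(letters[1:4], n / 4))
  covar <- cbind(age = rnorm(n))
  Y <- matrix(rnorm(n * 800), n)
  res <- ewas_ethnicity(Y, grp, covar)
  expect_gt(ks.test(res$p, "punif")$p.value, 0.01)
  expect_true(all(res$df1 == 3))   # 4 groups -> 3 numerator df
})

test_that("ethnicity scan detects injected shifts and flags Bonferroni", {
  set.seed(31)
  n <- 500
  grp <- factor(rep(c("mex", "pr"), each = n / 2))
  Y <- matrix(rnorm(n * 50, 0, 0.45), n)
  Y[, 1:10] <- Y[, 1:10] + 0.5 * as.numeric(grp == "mex")
  res <- ewas_ethnicity(Y, grp)
  # power oracle: delta 0.5, sd 0.45, n 500 -> noncentral F with ncp ~ 154;
  # detection at 1.6e-7 is essentially certain
  expect_true(all(res$p[1:10] < 1.6e-7))
  expect_true(all(res$significant[1:10]))
  expect_lt(mean(res$significant[11:50]), 0.05)
  # a level with < 2 samples is dropped with a warning
  grp2 <- as.character(grp); grp2[1] <- "single"
  expect_warning(ewas_ethnicity(Y, grp2), "single")
})

test_that("ancestry scan uses k-1 coding and attributes components", {
  set.seed(37)
  st <- tiny_study(seed = 37)
  M <- as_m_matrix(st$meth)
  res <- ewas_ancestry(M, st$q, st$sheet$ethnicity)
  expect_true(all(res$df1 == 2))   # 3 components -> 2 columns
  # theta CpGs carry a NAM effect: among significant hits, attribution NAM
  theta_cpgs <- attr(st$truth, "theta_cpgs")
  hit_theta <- res[res$probe %in% theta_cpgs & res$significant, ]
  if (nrow(hit_theta) > 0) {
    expect_gt(mean(hit_theta$driven_by == "NAM"), 0.8)
  }
  # permuted ancestry is null-calibrated (mean p not small)
  qperm <- st$q[sample(nrow(st$q)), ]
  rownames(qperm) <- rownames(st$q)
  res_p <- ewas_ancestry(M[, !colnames(M) %in%
                             c(attr(st$truth, "theta_cpgs"),
                               attr(st$truth, "meqtl_cpgs"))],
                         qperm, st$sheet$ethnicity)
  expect_gt(ks.test(res_p$p, "punif")$p.value, 0.001)
})

test_that("injected ancestry effect is detected at the oracle power", {
  # theta_AFR = 1.0 at n = 500, sd 0.45, ethnicity-adjusted 2-df test at
  # the 1.6e-7 genome-wide threshold. Detection frequency must match the
  # exact noncentral-F power computed from the realized design.
  set.seed(41)
  prof <- default_profiles(250, 250)
  q <- rbind(simulate_global_ancestry(prof$Mexican),
             simulate_global_ancestry(prof$PuertoRican))
  eth <- rep(c("mex", "pr"), each = 250)
  thr <- 1.6e-7
  X_red <- cbind(1, as.numeric(eth == "pr"))
  block <- q[, c("AFR", "NAM")]
  signal <- 1.0 * q[, "AFR"]
  # conditional noncentrality: ||P_block (I - P_red) signal||^2 / sigma^2
  r_sig <- qr.resid(qr(X_red), signal)
  proj <- qr.fitted(qr(qr.resid(qr(X_red), block)), r_sig)
  ncp <- sum(proj^2) / 0.45^2
  df2 <- 500 - 4
  power <- pf(qf(1 - thr, 2, df2), 2, df2, ncp = ncp, lower.tail = FALSE)
  reps <- 40
  det <- logical(reps); attrib <- character(reps)
  for (r in seq_len(reps)) {
    y <- signal + rnorm(500, 0, 0.45)
    res <- ewas_ancestry(matrix(y, ncol = 1), q, eth)
    det[r] <- res$p < thr
    attrib[r] <- res$driven_by
  }
  expect_lt(abs(mean(det) - power),
            3 * sqrt(max(power * (1 - power), 0.25 / reps) / reps) + 0.05)
  # the signal is attributed to African ancestry
  expect_gt(mean(attrib == "AFR"), 0.8)
})

test_that("stability flag trips on collinearity, not mere correlation", {
  set.seed(43)
  n <- 500
  x <- rnorm(n)
  y <- rnorm(n)
  X_un <- cbind(`(Intercept)` = 1, ethnicityB = x)
  # orthogonal addition: stable
  f_un <- fit_ols(y, X_un)
  f_ad <- fit_ols(y, cbind(X_un, z = rnorm(n)))
  expect_false(stability_flag(f_ad, f_un))
  # near-duplicate column (just above the QR rank tolerance): unstable
  f_dup <- fit_ols(y, cbind(X_un, z = x + rnorm(n, 0, 1e-6)))
  expect_true(stability_flag(f_dup, f_un))
  # an exactly duplicated column is caught earlier as a rank error
  expect_error(fit_ols(y, cbind(X_un, z = x)), "rank deficient")
  # correlation 0.9 at n = 500: VIF ~ 1/(1-0.81) ~ 5 << 100, stable
  z <- 0.9 * scale(x)[, 1] + sqrt(1 - 0.81) * rnorm(n)
  f_cor <- fit_ols(y, cbind(X_un, z = z))
  expect_false(stability_flag(f_cor, f_un))
})

test_that("non-linearity screen has correct df, calibration and power", {
  set.seed(47)
  n <- 500
  anc <- runif(n)
  covar <- cbind(c1 = rnorm(n))
  # spline block adds exactly 3 columns
  expect_equal(ncol(admixmeth:::spline_block(anc)), 3L)
  # linear truth: p uniform over replicates
  pvals <- replicate(200, {
    y <- 0.8 * anc + rnorm(n, 0, 0.45)
    nonlinearity_test(y, anc, covar, method = "poly")$p_nonlinear
  })
  expect_gt(ks.test(pvals, "punif")$p.value, 0.01)
  # quadratic truth at 1 M-unit: detection frequency must match the exact
  # noncentral-F power computed from the realized ancestry vector
  signal <- 1 * anc^2
  resid_sig <- qr.resid(qr(cbind(1, covar, anc)), signal)
  power_for <- function(block, df1) {
    ncp <- sum(qr.fitted(qr(block), resid_sig)^2) / 0.45^2
    df2 <- n - 3 - df1
    pf(qf(0.95, df1, df2), df1, df2, ncp = ncp, lower.tail = FALSE)
  }
  reps <- 80
  hits <- replicate(reps, {
    y <- signal + rnorm(n, 0, 0.45)
    nonlinearity_test(y, anc, covar, method = "poly")$p_nonlinear < 0.05
  })
  pw <- power_for(cbind(anc^2, anc^3) |>
                    (\(B) qr.resid(qr(cbind(1, covar, anc)), B))(), 2)
  expect_lt(abs(mean(hits) - pw), 3 * sqrt(pw * (1 - pw) / reps) + 0.03)
  hits_sp <- replicate(reps, {
    y <- signal + rnorm(n, 0, 0.45)
    nonlinearity_test(y, anc, covar, method = "spline")$p_nonlinear < 0.05
  })
  pw_sp <- power_for(admixmeth:::spline_block(anc), 3)
  expect_lt(abs(mean(hits_sp) - pw_sp),
            3 * sqrt(pw_sp * (1 - pw_sp) / reps) + 0.03)
  # ethnicity re-test is returned when requested
  eth <- rep(c("a", "b"), each = n / 2)
  y2 <- 0.5 * (eth == "a") + anc^2 + rnorm(n, 0, 0.45)
  out <- nonlinearity_test(y2, anc, covar, ethnicity = eth,
                           method = "spline")
  expect_lt(out$p_ethnicity, 1e-6)
  expect_error(nonlinearity_test(y2, rep(1, n), covar), "unique")
})

test_that("Bonferroni thresholds reproduce the printed values", {
  expect_equal(signif(bonferroni(0.05, 321503), 2), 1.6e-7)
  expect_equal(bonferroni(0.05, 1), 0.05)
  expect_equal(signif(bonferroni(0.05, 4404), 2), 1.1e-5)
})

test_that("fold-change conversion is base 2", {
  expect_equal(round(m_to_fold(2.7), 1), 6.5)
  expect_equal(m_to_fold(0), 1)
  expect_equal(m_to_fold(1), 2)
})

test_that("enrichment computes binomial and hypergeometric tails", {
  universe <- sprintf("cg%05d", 1:5000)
  # 1341 of 4404 nominal at rate 0.05: astronomically enriched
  p_map <- setNames(rep(0.5, 5000), universe)
  cand <- universe[1:4404]
  p_map[cand[1:1341]] <- 0.01
  res <- enrichment(hit_set = character(0), candidate_set = cand,
                    universe = universe, nominal_p_map = p_map)
  expect_equal(res$n_nominal, 1341L)
  expect_equal(round(100 * res$nominal_rate, 1), 30.4)
  expect_lt(res$binom_p, 2e-16)

  # 0 of 100 nominal -> p ~ 1
  p_map2 <- setNames(rep(0.5, 5000), universe)
  res2 <- enrichment(character(0), universe[1:100], universe, p_map2)
  expect_gt(res2$binom_p, 0.99)

  # hypergeometric tail by full enumeration: overlap 3, cands 5, hits 10,
  # universe 50
  hits <- universe[1:10]
  cand3 <- c(universe[1:3], universe[21:22])
  res3 <- enrichment(hits, cand3, universe[1:50], p_map[1:50])
  enum <- sum(vapply(3:5, function(k) {
    choose(10, k) * choose(40, 5 - k) / choose(50, 5)
  }, numeric(1)))
  expect_equal(res3$hyper_p, enum, tolerance = 1e-12)

  expect_error(enrichment(hits, character(0), universe, p_map), "empty")
  expect_error(enrichment(hits, "not_in_universe", universe, p_map),
               "subset")
})

test_that("admixture mapping recovers per-haplotype effects", {
  set.seed(53)
  st <- tiny_study(seed = 53, duffy = TRUE, duffy_beta = 1.35)
  duffy_cpg <- attr(st$truth, "duffy_cpg")
  M <- as_m_matrix(st$meth)
  pos <- st$truth$cpgs$pos_gen[match(duffy_cpg, st$truth$cpgs$probe)]
  dos <- local_dosage_at(st$tracts, pos)
  am <- admixture_map(M[, duffy_cpg], dos)
  afr <- am$effects[am$effects$ancestry == "AFR", ]
  expect_lt(abs(afr$beta - 1.35), 2 * afr$se)
  expect_lt(am$omnibus$p, 1e-10)
  # fold-change contract: effect in M units convertible
  expect_equal(m_to_fold(afr$beta), 2^afr$beta)
  # constant dosage errors
  dos0 <- dos; dos0[, ] <- rep(c(2, 0, 0), each = nrow(dos0))
  expect_error(admixture_map(M[, duffy_cpg], dos0), "variance")
})

test_that("cis scan ranks the causal SNP and respects window bounds", {
  set.seed(59)
  st <- tiny_study(seed = 59, duffy = TRUE, duffy_beta = 1.35)
  duffy_cpg <- attr(st$truth, "duffy_cpg")
  duffy_snp <- attr(st$truth, "duffy_snp")
  j <- match(duffy_cpg, st$truth$cpgs$probe)
  M <- as_m_matrix(st$meth)
  res <- cis_scan(M[, duffy_cpg], st$geno, st$truth$cpgs$pos_bp[j],
                  window_bp = 10000)
  expect_equal(res$table$snp[1], duffy_snp)

  # empty window returns an empty table
  far <- cis_scan(M[, duffy_cpg], st$geno,
                  max(st$geno$snps$pos_bp) + 1e6, window_bp = 10)
  expect_equal(nrow(far$table), 0L)

  # window boundaries inclusive at exactly +/- window_bp
  target <- st$geno$snps$pos_bp[5]
  at <- cis_scan(M[, duffy_cpg], st$geno, target + 10000,
                 window_bp = 10000)
  expect_true(st$geno$snps$snp[5] %in% at$table$snp)
})
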