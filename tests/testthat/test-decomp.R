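# Variance partitioning and mediation.

test_that("block PVE reduces to the closed forms", {
  # y = x exactly -> PVE 1
  x <- c(-2, -1, 0, 1, 2, 4)
  f <- fit_ols(x, cbind(`(Intercept)` = 1, x = x))
  expect_equal(pve_block(f, "x", x), 1)

  # hand-listed 6 points: PVE = beta^2 Sxx / Syy
  y <- c(1.2, 0.8, 2.4, 2.0, 3.1, 4.8)
  f2 <- fit_ols(y, cbind(`(Intercept)` = 1, x = x))
  beta <- f2$coefficients[["x"]]
  expect_equal(pve_block(f2, "x", y),
               beta^2 * var(x) / var(y))

  # orthogonal blocks: PVEs sum to overall R^2 (ANOVA decomposition)
  set.seed(3)
  n <- 200
  a <- rnorm(n); b <- rnorm(n)
  b <- qr.resid(qr(cbind(1, a)), b)          # exactly orthogonal to a
  yy <- 0.7 * a + 0.4 * b + rnorm(n)
  f3 <- fit_ols(yy, cbind(`(Intercept)` = 1, a = a, b = b))
  r2 <- 1 - f3$rss / sum((yy - mean(yy))^2)
  expect_equal(pve_block(f3, "a", yy) + pve_block(f3, "b", yy), r2,
               tolerance = 1e-10)

  # affine rescaling of y leaves PVE unchanged
  f4 <- fit_ols(5 * y + 3, cbind(`(Intercept)` = 1, x = x))
  expect_equal(pve_block(f4, "x", 5 * y + 3), pve_block(f2, "x", y))

  expect_error(pve_block(f2, "x", rep(1, 6)), "zero variance")
})

test_that("joint partition attributes variance to the causal block", {
  prof <- default_profiles(1000, 1000)
  set.seed(7)
  q <- rbind(simulate_global_ancestry(prof$Mexican),
             simulate_global_ancestry(prof$PuertoRican))
  eth <- rep(c("mex", "pr"), each = 1000)

  # ancestry-only effect: ancestry share -> ~1 at large n (ethnicity and
  # NAM ancestry are heavily collinear here, so the share is averaged over
  # replicates; the strong effect keeps coefficient noise subdominant)
  sh <- replicate(5, {
    vp <- joint_partition(3 * q[, "NAM"] + rnorm(2000, 0, 0.45), eth, q)
    expect_true(vp$stable)
    vp$ancestry_share
  })
  expect_gt(mean(sh), 0.85)

  # ethnicity-only effect: ancestry share -> ~0
  sh0 <- replicate(5, {
    joint_partition(0.5 * (eth == "mex") + rnorm(2000, 0, 0.45), eth,
                    q)$ancestry_share
  })
  expect_lt(mean(sh0), 0.2)
  vp2 <- joint_partition(0.5 * (eth == "mex") + rnorm(2000, 0, 0.45),
                         eth, q)

  # pure noise: joint PVE ~ E[R^2 | null] = p_design / (n - 1)
  y0 <- rnorm(2000)
  vp0 <- joint_partition(y0, eth, q)
  expect_lt(abs(vp0$joint - 3 / 1999), 3 * sqrt(2 * 3) / 1999)

  # shares always within [0, 1]
  expect_true(all(c(sh, sh0, vp2$ancestry_share, vp0$ancestry_share) >= 0))
  expect_true(all(c(sh, sh0, vp2$ancestry_share, vp0$ancestry_share) <= 1))
})

test_that("local/global partition separates cis from trans effects", {
  # fixed-difference locus: the genotype is a deterministic function of
  # local African ancestry, so a cis-driven outcome loads on the local block
  st <- tiny_study(seed = 71, n_mex = 150, n_pr = 120, duffy = TRUE)
  duffy_cpg <- attr(st$truth, "duffy_cpg")
  j <- match(duffy_cpg, st$truth$cpgs$probe)
  dos <- local_dosage_at(st$tracts, st$truth$cpgs$pos_gen[j])
  g <- st$geno$dosages[, st$truth$meqtl_snp[j]]
  y_cis <- 1.35 * g + rnorm(nrow(dos), 0, 0.45)
  vp <- local_global_partition(y_cis, dos, st$q, ref = "NAM")
  expect_true(vp$stable)
  expect_gt(vp$local_share, 0.5)

  # global-only effect: local share below 0.5 (only ancestry LD links it)
  y_glob <- 1.2 * st$q[, "NAM"] + rnorm(nrow(dos), 0, 0.45)
  vp2 <- local_global_partition(y_glob, dos, st$q)
  expect_lt(vp2$local_share, 0.5)
  expect_true(vp2$local_share >= 0 && vp2$local_share <= 1)
})

test_that("mediation recovers the product-of-coefficients identities", {
  set.seed(11)
  n <- 400
  tr <- rep(0:1, each = n / 2)
  # noiseless linear system a = 0.5, b = 1.0, c' = 0.2: the mediator noise
  # is orthogonalized against the treatment so the fitted coefficients are
  # exact and the product identities hold to machine precision
  e <- qr.resid(qr(cbind(1, tr)), rnorm(n, 0, 0.3))
  m <- 0.5 * tr + e
  y <- 0.2 * tr + 1.0 * m
  res <- mediate(y, tr, m, n_sims = 500, seed = 1)
  expect_equal(res$acme, 0.5, tolerance = 1e-8)
  expect_equal(res$total, 0.7, tolerance = 1e-8)
  expect_equal(round(res$prop_mediated, 3), 0.714)

  # b = 0: proportion mediated ~ 0, CI covers 0
  m2 <- 0.5 * tr + rnorm(n, 0, 0.3)
  y2 <- 0.4 * tr + 0 * m2 + rnorm(n, 0, 0.3)
  res2 <- mediate(y2, tr, m2, n_sims = 1000, seed = 2)
  expect_lt(abs(res2$prop_mediated_raw), 0.15)
  expect_true(res2$acme_ci[1] <= 0 && res2$acme_ci[2] >= 0)

  # seeded reproducibility; ACME + ADE = total exactly (linear case)
  res3a <- mediate(y2, tr, m2, n_sims = 200, seed = 9)
  res3b <- mediate(y2, tr, m2, n_sims = 200, seed = 9)
  expect_identical(res3a$acme_ci, res3b$acme_ci)
  expect_equal(res3a$acme + res3a$ade, res3a$total)

  expect_error(mediate(y2, rep(0:2, length.out = n), m2), "binary")
})
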