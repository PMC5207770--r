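# Variance partitioning (ethnicity vs global ancestry vs fine structure vs
# local ancestry) and causal mediation of ethnicity effects by ancestry.
#
# Block PVE is defined as Var(X_b beta_b) / Var(y) — the sample variance of
# the block's fitted contribution over the sample variance of the outcome.
# For a single standardized predictor this reduces to beta^2 Var(x)/Var(y),
# the familiar squared-correlation form. Cross-block covariance is assigned
# only to the joint term, so sub-block PVEs need not sum to the joint PVE.

#' Proportion of variance explained by a design block
#'
#' @param fit A `model_fit` from [fit_ols()].
#' @param block Column names of the block within the fit's design.
#' @param y The outcome the model was fitted to.
#' @return `Var(X_block beta_block) / Var(y)` (sample variances).
#' @export
pve_block <- function(fit, block, y) {
  stopifnot(inherits(fit, "model_fit"),
            all(block %in% colnames(fit$design)))
  vy <- stats::var(y)
  if (vy == 0) abort_admix("outcome has zero variance", "admixmeth_invalid")
  contrib <- fit$design[, block, drop = FALSE] %*%
    fit$coefficients[block]
  as.numeric(stats::var(contrib) / vy)
}

#' Joint variance partition: ethnicity and global ancestry
#'
#' Fits the joint model (covariates + ethnicity indicators + K-1 ancestry
#' columns) and reports the PVE of the combined ethnicity+ancestry block,
#' the two sub-block PVEs from the same joint fit, and the ancestry share
#' of the joint PVE (truncated to \[0, 1\]). A collinear joint design
#' yields `stable = FALSE` and no shares.
#'
#' @param y M-values at one CpG.
#' @param ethnicity Ethnicity factor.
#' @param q Samples x K global-ancestry matrix.
#' @param covariates Covariate matrix.
#' @param ref Reference ancestry dropped from the compositional block.
#' @return List of class `variance_partition`: `joint`, `ethnicity`,
#'   `ancestry`, `ancestry_share`, `stable`.
#' @export
joint_partition <- function(y, ethnicity, q, covariates = NULL,
                            ref = "EUR") {
  eth_block <- indicator_columns(droplevels(as.factor(ethnicity)),
                                 "ethnicity")
  anc_block <- compositional_columns(q, ref = ref)
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates, eth_block,
             anc_block)
  fit <- tryCatch(fit_ols(y, X), error = function(e) NULL)
  if (is.null(fit)) {
    return(structure(list(joint = NA_real_, ethnicity = NA_real_,
                          ancestry = NA_real_, ancestry_share = NA_real_,
                          stable = FALSE),
                     class = "variance_partition"))
  }
  joint <- pve_block(fit, c(colnames(eth_block), colnames(anc_block)), y)
  eth <- pve_block(fit, colnames(eth_block), y)
  anc <- pve_block(fit, colnames(anc_block), y)
  share <- if (joint > 0) min(max(anc / joint, 0), 1) else NA_real_
  structure(list(joint = joint, ethnicity = eth, ancestry = anc,
                 ancestry_share = share, stable = TRUE),
            class = "variance_partition")
}

#' Variance partition: local versus global ancestry
#'
#' As [joint_partition()] with blocks {local-ancestry dosage at the CpG}
#' and {global-ancestry proportions}, quantifying how much of the ancestry
#' effect acts in cis through the local haplotype.
#'
#' @param y M-values at one CpG.
#' @param local_dosage Individuals x K local-ancestry dosage at the CpG.
#' @param q Samples x K global-ancestry matrix.
#' @param covariates Covariate matrix.
#' @param ref Reference ancestry.
#' @return List of class `variance_partition`: `joint`, `local`, `global`,
#'   `local_share`, `stable`.
#' @export
local_global_partition <- function(y, local_dosage, q, covariates = NULL,
                                   ref = "EUR") {
  loc <- compositional_columns(local_dosage, ref = ref)
  colnames(loc) <- paste0("local_", colnames(loc))
  loc <- loc[, apply(loc, 2L, stats::var) > 0, drop = FALSE]
  glo <- compositional_columns(q, ref = ref)
  colnames(glo) <- paste0("global_", colnames(glo))
  X <- cbind(`(Intercept)` = rep(1, length(y)), covariates, loc, glo)
  fit <- tryCatch(fit_ols(y, X), error = function(e) NULL)
  if (is.null(fit) || ncol(loc) == 0L) {
    return(structure(list(joint = NA_real_, local = NA_real_,
                          global = NA_real_, local_share = NA_real_,
                          stable = FALSE),
                     class = "variance_partition"))
  }
  joint <- pve_block(fit, c(colnames(loc), colnames(glo)), y)
  local <- pve_block(fit, colnames(loc), y)
  global <- pve_block(fit, colnames(glo), y)
  share <- if (joint > 0) min(max(local / joint, 0), 1) else NA_real_
  structure(list(joint = joint, local = local, global = global,
                 local_share = share, stable = TRUE),
            class = "variance_partition")
}

#' Causal mediation of a binary contrast by a continuous mediator
#'
#' Product-of-coefficients mediation with quasi-Bayesian uncertainty.
#' Fits the mediator model `m ~ a t + covariates` and the outcome model
#' `y ~ c' t + b m + covariates`; the average causal mediation effect is
#' `ACME = a b`, the direct effect `ADE = c'`, the total effect
#' `a b + c'`. Uncertainty comes from `n_sims` draws of the coefficient
#' vectors from their asymptotic normal distributions; percentile
#' confidence intervals and the two-sided simulation p-value
#' `2 min(Pr(ACME <= 0), Pr(ACME >= 0))` are reported. The proportion
#' mediated is `ACME / total`, reported truncated to \[0, 1\] (the
#' untruncated value is retained).
#'
#' @param y Outcome (e.g. a methylation principal coordinate).
#' @param treatment Binary treatment vector (0/1), e.g. the contrast
#'   between the two largest ethnic groups.
#' @param mediator Continuous mediator (e.g. an ancestry proportion).
#' @param covariates Covariate matrix.
#' @param n_sims Number of quasi-Bayesian draws.
#' @param level Confidence level for percentile intervals.
#' @param seed RNG seed.
#' @return List of class `mediation_result`: `acme`, `ade`, `total`,
#'   `prop_mediated` (truncated), `prop_mediated_raw`, `acme_ci`,
#'   `ade_ci`, `total_ci`, `prop_ci`, `acme_p`, `n_sims`, `seed`.
#' @export
mediate <- function(y, treatment, mediator, covariates = NULL,
                    n_sims = 1000, level = 0.95, seed = NULL) {
  t_vals <- sort(unique(treatment))
  if (length(t_vals) != 2L) {
    abort_admix("treatment must be binary; recode multi-group ethnicity as a pairwise contrast",
                "admixmeth_invalid")
  }
  tr <- as.numeric(treatment == t_vals[2L])
  n <- length(y)
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    # indicator levels can empty out when the contrast subsets the cohort
    covariates <- covariates[, apply(covariates, 2L, stats::var) > 0,
                             drop = FALSE]
  }
  X_m <- cbind(`(Intercept)` = rep(1, n), treatment = tr, covariates)
  X_y <- cbind(`(Intercept)` = rep(1, n), treatment = tr,
               mediator = mediator, covariates)
  fit_m <- fit_ols(mediator, X_m)
  fit_y <- fit_ols(y, X_y)
  a_hat <- fit_m$coefficients[["treatment"]]
  b_hat <- fit_y$coefficients[["mediator"]]
  c_hat <- fit_y$coefficients[["treatment"]]
  acme <- a_hat * b_hat
  ade <- c_hat
  total <- acme + ade
  draws <- with_seed(seed, {
    a_s <- draw_coef(fit_m, n_sims)[, "treatment"]
    cb <- draw_coef(fit_y, n_sims)
    cbind(acme = a_s * cb[, "mediator"], ade = cb[, "treatment"])
  })
  sim_acme <- draws[, "acme"]
  sim_ade <- draws[, "ade"]
  sim_total <- sim_acme + sim_ade
  sim_prop <- ifelse(sim_total == 0, NA_real_, sim_acme / sim_total)
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  prop_raw <- if (total == 0) NA_real_ else acme / total
  structure(list(
    acme = acme, ade = ade, total = total,
    prop_mediated = min(max(prop_raw, 0), 1),
    prop_mediated_raw = prop_raw,
    acme_ci = stats::quantile(sim_acme, probs, names = FALSE),
    ade_ci = stats::quantile(sim_ade, probs, names = FALSE),
    total_ci = stats::quantile(sim_total, probs, names = FALSE),
    prop_ci = pmin(pmax(stats::quantile(sim_prop, probs, names = FALSE,
                                        na.rm = TRUE), 0), 1),
    acme_p = 2 * min(mean(sim_acme <= 0), mean(sim_acme >= 0)),
    n_sims = n_sims, seed = seed
  ), class = "mediation_result")
}

# quasi-Bayesian coefficient draws: MVN around the OLS estimate with the
# estimated covariance
draw_coef <- function(fit, n_sims) {
  V <- fit_vcov(fit)
  MASS::mvrnorm(n_sims, mu = fit$coefficients, Sigma = V)
}

fit_vcov <- function(fit) {
  qx <- qr(fit$design)
  xtx_inv <- chol2inv(qr.R(qx))[order(qx$pivot), order(qx$pivot)]
  sigma2 <- fit$rss / fit$df
  V <- xtx_inv * sigma2
  dimnames(V) <- list(colnames(fit$design), colnames(fit$design))
  V
}

#' @export
print.mediation_result <- function(x, ...) {
  cat(sprintf(
    "mediation: ACME %.4f [%.4f, %.4f] (p=%.3g), ADE %.4f, total %.4f\n",
    x$acme, x$acme_ci[1], x$acme_ci[2], x$acme_p, x$ade, x$total))
  cat(sprintf("proportion mediated %.3f [%.3f, %.3f]\n",
              x$prop_mediated, x$prop_ci[1], x$prop_ci[2]))
  invisible(x)
}
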