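# Per-CpG association machinery: OLS fits, nested-ANOVA omnibus tests,
# ethnicity and global-ancestry scans, stability and non-linearity screens,
# admixture mapping, conditional cis-SNP scans, Bonferroni thresholds, and
# enrichment against exposure-associated CpG sets.
#
# All tests run on M-values. The "likelihood-ratio" omnibus tests are
# implemented as nested-ANOVA F tests (asymptotically equivalent for
# Gaussian OLS), one inference engine throughout.

#' Ordinary least squares fit
#'
#' @param y Response vector.
#' @param design Numeric design matrix with column names (include the
#'   intercept column explicitly).
#' @return A `model_fit`: coefficients, standard errors, `rss`, residual
#'   `df`, `rank`, `n`, and the design (for downstream diagnostics).
#'   Rank-deficient designs raise an error naming the dependent columns.
#' @export
fit_ols <- function(y, design) {
  stopifnot(is.numeric(y), is.matrix(design), nrow(design) == length(y))
  if (is.null(colnames(design))) {
    colnames(design) <- paste0("x", seq_len(ncol(design)))
  }
  qx <- qr(design)
  if (qx$rank < ncol(design)) {
    dep <- colnames(design)[qx$pivot[(qx$rank + 1):ncol(design)]]
    abort_admix(paste("design is rank deficient; dependent columns:",
                      paste(dep, collapse = ", ")), "admixmeth_rank")
  }
  coef <- qr.coef(qx, y)
  res <- qr.resid(qx, y)
  rss <- sum(res^2)
  df <- length(y) - qx$rank
  if (df < 1L) abort_admix("no residual degrees of freedom",
                           "admixmeth_invalid")
  xtx_inv_diag <- diag(chol2inv(qr.R(qx)))[order(qx$pivot)]
  se <- sqrt(pmax(xtx_inv_diag, 0) * rss / df)
  names(se) <- colnames(design)
  structure(list(coefficients = coef, se = se, rss = rss, df = df,
                 rank = qx$rank, n = length(y), design = design),
            class = "model_fit")
}

#' Nested analysis of variance
#'
#' Omnibus F-test comparing a full model against a reduced model nested
#' within it: `F = ((RSS_r - RSS_f)/df1) / (RSS_f/df2)`.
#'
#' @param full,reduced `model_fit` objects; the reduced design columns must
#'   be a subset of the full design columns (checked by name).
#' @return List with `F`, `df1`, `df2`, `p`. Identical models give
#'   `F = 0, p = 1`.
#' @export
nested_anova <- function(full, reduced) {
  stopifnot(inherits(full, "model_fit"), inherits(reduced, "model_fit"))
  if (full$n != reduced$n ||
      !all(colnames(reduced$design) %in% colnames(full$design))) {
    abort_admix("models are not nested", "admixmeth_invalid")
  }
  df1 <- full$rank - reduced$rank
  df2 <- full$df
  if (df1 == 0L) return(list(F = 0, df1 = 0L, df2 = df2, p = 1))
  if (df1 < 0L || reduced$rss < full$rss - 1e-8 * max(1, full$rss)) {
    abort_admix("models are not nested", "admixmeth_invalid")
  }
  Fstat <- ((reduced$rss - full$rss) / df1) / (full$rss / df2)
  list(F = Fstat, df1 = df1, df2 = df2,
       p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

# vectorized omnibus scan over the columns of Y: F-test of adding `block`
# to the reduced design. Returns data frame (F, df1, df2, p).
omnibus_scan <- function(Y, X_red, block) {
  X_full <- cbind(X_red, block)
  q_red <- qr(X_red)
  q_full <- qr(X_full)
  if (q_red$rank < ncol(X_red)) {
    abort_admix("reduced design is rank deficient", "admixmeth_rank")
  }
  rss_red <- colSums(qr.resid(q_red, Y)^2)
  rss_full <- colSums(qr.resid(q_full, Y)^2)
  df1 <- q_full$rank - q_red$rank
  df2 <- nrow(Y) - q_full$rank
  Fstat <- ((rss_red - rss_full) / df1) / (rss_full / df2)
  data.frame(F = Fstat, df1 = df1, df2 = df2,
             p = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Standard covariate design for the methylation models
#'
#' Builds the adjustment block used throughout: case status, age, sex, cell
#' proportions (k-1 columns, reference cell type dropped — compositional
#' coding), and plate and position indicators.
#'
#' @param sheet Sample sheet with columns `case`, `age`, `sex`, `plate`,
#'   `position`.
#' @param cells Optional samples x cell-types proportion matrix.
#' @param cell_ref Reference cell type dropped from the compositional block.
#' @return Numeric covariate matrix (no intercept column).
#' @export
covariate_design <- function(sheet, cells = NULL,
                             cell_ref = "Granulocyte") {
  X <- cbind(case = as.numeric(sheet$case),
             age = as.numeric(sheet$age),
             indicator_columns(sheet$sex, "sex"),
             indicator_columns(sheet$plate, "plate"),
             indicator_columns(sheet$position, "position"))
  if (!is.null(cells)) {
    X <- cbind(X, compositional_columns(cells, ref = cell_ref))
  }
  X
}

#' Epigenome-wide scan of self-identified ethnicity
#'
#' Per CpG, an omnibus nested-ANOVA test of all ethnicity indicators
#' (levels - 1 numerator df) against the covariate-only model, with a
#' Bonferroni significance flag at `alpha / n_probes`. Ethnicity levels
#' with fewer than 2 samples are dropped with a warning. Supplying
#' `ancestry` (K-1 columns added to both models) gives the
#' ancestry-adjusted ethnicity scan.
#'
#' @param m Samples x probes matrix of M-values, or a [meth_matrix()]
#'   (beta input is converted).
#' @param ethnicity Per-sample ethnicity factor.
#' @param covariates Covariate matrix from [covariate_design()].
#' @param ancestry Optional samples x (K-1) global-ancestry columns to
#'   adjust for (see [compositional_columns()]).
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return Data frame of class `association_result`: probe, F, df1, df2, p,
#'   significant; the threshold is attached as attribute `"threshold"`.
#' @export
ewas_ethnicity <- function(m, ethnicity, covariates = NULL, ancestry = NULL,
                           alpha = 0.05) {
  Y <- as_m_matrix(m)
  eth <- droplevels(as.factor(ethnicity))
  small <- table(eth) < 2L
  if (any(small)) {
    warning("ethnicity levels dropped (<2 samples): ",
            paste(names(which(small)), collapse = ", "))
    keep <- !(eth %in% names(which(small)))
    Y <- Y[keep, , drop = FALSE]
    eth <- droplevels(eth[keep])
    covariates <- covariates[keep, , drop = FALSE]
    ancestry <- ancestry[keep, , drop = FALSE]
  }
  if (nlevels(eth) < 2L) {
    abort_admix("ethnicity must have at least 2 levels", "admixmeth_invalid")
  }
  X_red <- cbind(`(Intercept)` = rep(1, nrow(Y)), covariates, ancestry)
  block <- indicator_columns(eth, "ethnicity")
  res <- omnibus_scan(Y, X_red, block)
  finalize_scan(res, colnames(Y), alpha)
}

#' Epigenome-wide scan of global genetic ancestry
#'
#' Per CpG, a (K-1)-df omnibus test of the global-ancestry proportions
#' (European reference component dropped) adjusted for ethnicity and
#' covariates, plus per-component marginal tests; each hit is attributed to
#' the ancestry with the smallest marginal p ("driven primarily by").
#'
#' @param m M-value matrix or [meth_matrix()].
#' @param q Samples x K global-ancestry proportion matrix (named columns).
#' @param ethnicity Per-sample ethnicity factor (adjusted for).
#' @param covariates Covariate matrix.
#' @param ref Reference ancestry dropped from the compositional block.
#' @param alpha Family-wise error rate for the Bonferroni flag.
#' @return `association_result` data frame: probe, F, df1, df2, p,
#'   per-component marginal p columns (`p_AFR`, ...), `driven_by`,
#'   significant.
#' @export
ewas_ancestry <- function(m, q, ethnicity = NULL, covariates = NULL,
                          ref = "EUR", alpha = 0.05) {
  Y <- as_m_matrix(m)
  stopifnot(is.matrix(q), !is.null(colnames(q)))
  X_red <- cbind(`(Intercept)` = rep(1, nrow(Y)), covariates)
  if (!is.null(ethnicity)) {
    X_red <- cbind(X_red, indicator_columns(as.factor(ethnicity),
                                            "ethnicity"))
  }
  block <- compositional_columns(q, ref = ref)
  res <- omnibus_scan(Y, X_red, block)
  marg <- vapply(colnames(q), function(k) {
    omnibus_scan(Y, X_red, q[, k, drop = FALSE])$p
  }, numeric(ncol(Y)))
  if (is.null(dim(marg))) marg <- matrix(marg, nrow = 1L,
                                         dimnames = list(NULL, colnames(q)))
  colnames(marg) <- paste0("p_", colnames(q))
  res <- cbind(res, marg)
  res$driven_by <- colnames(q)[apply(marg, 1L, which.min)]
  finalize_scan(res, colnames(Y), alpha)
}

#' Coerce methylation input to a plain M-value matrix
#'
#' Accepts a [meth_matrix()] (beta values are logit2-transformed) or a
#' plain numeric matrix assumed to already be on the M scale.
#'
#' @param m A `meth_matrix` or samples x probes numeric matrix.
#' @return Samples x probes matrix of M-values.
#' @export
as_m_matrix <- function(m) {
  if (inherits(m, "meth_matrix")) {
    v <- m$values
    if (m$scale == "beta") v <- beta_to_m(v)
    return(v)
  }
  stopifnot(is.matrix(m))
  if (is.null(colnames(m))) colnames(m) <- paste0("cpg", seq_len(ncol(m)))
  m
}

finalize_scan <- function(res, probes, alpha) {
  thr <- bonferroni(alpha, nrow(res))
  out <- cbind(data.frame(probe = probes, stringsAsFactors = FALSE), res)
  out$significant <- out$p < thr
  attr(out, "threshold") <- thr
  class(out) <- c("association_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Bonferroni significance threshold
#'
#' @param alpha Family-wise error rate.
#' @param n_tests Number of tests (>= 1).
#' @return `alpha / n_tests`.
#' @export
bonferroni <- function(alpha, n_tests) {
  stopifnot(alpha > 0, alpha <= 1, n_tests >= 1)
  alpha / n_tests
}

#' M-value difference to fold change
#'
#' An M-value difference `d` corresponds to a `2^d`-fold change in the
#' ratio of methylated to unmethylated DNA.
#'
#' @param delta_m M-value difference.
#' @return Fold change `2^delta_m`.
#' @export
m_to_fold <- function(delta_m) 2^delta_m

#' Coefficient-stability flag
#'
#' Flags fits where adjustment has destabilized the ethnicity coefficients:
#' any shared coefficient whose standard error grew by more than
#' `se_ratio_cut` between the unadjusted and adjusted fits, or any adjusted
#' ethnicity design column with variance-inflation factor above `vif_cut`
#' (collinearity of ethnicity with ancestry).
#'
#' @param fit_adj,fit_unadj `model_fit` objects sharing ethnicity columns.
#' @param cols Names of the ethnicity columns to inspect (default: columns
#'   present in both designs whose name starts with "ethnicity").
#' @param vif_cut,se_ratio_cut Thresholds.
#' @return `TRUE` if the adjusted fit is unstable.
#' @export
stability_flag <- function(fit_adj, fit_unadj, cols = NULL, vif_cut = 100,
                           se_ratio_cut = 10) {
  shared <- intersect(colnames(fit_adj$design), colnames(fit_unadj$design))
  if (is.null(cols)) cols <- grep("^ethnicity", shared, value = TRUE)
  if (length(cols) == 0L) cols <- setdiff(shared, "(Intercept)")
  ratio <- fit_adj$se[cols] / fit_unadj$se[cols]
  any(ratio > se_ratio_cut) || any(design_vif(fit_adj$design, cols) >
                                     vif_cut)
}

# VIF of selected design columns: 1 / (1 - R^2) of each column regressed on
# all the others (intercept not counted as a predictor of itself)
design_vif <- function(X, cols) {
  idx <- if (is.character(cols)) match(cols, colnames(X)) else cols
  vapply(idx, function(j) {
    x <- X[, j]
    r <- qr.resid(qr(X[, -j, drop = FALSE]), x)
    ss_tot <- sum((x - mean(x))^2)
    if (ss_tot == 0) return(Inf)
    1 / max(sum(r^2) / ss_tot, 1e-300)
  }, numeric(1))
}

#' Classify ethnicity hits after ancestry adjustment
#'
#' Partitions the Bonferroni-significant CpGs of the unadjusted ethnicity
#' scan into `"remains"` (still significant after ancestry adjustment),
#' `"explained"` (no longer significant), and `"unstable"` (excluded
#' because adjustment inflated the ethnicity coefficient standard errors).
#'
#' @param unadjusted,adjusted `association_result` data frames over the
#'   same probes (from [ewas_ethnicity()] without and with `ancestry`).
#' @param unstable Logical vector (per probe) of stability exclusions,
#'   e.g. from [scan_stability()].
#' @param threshold Significance threshold for "remains" (default: the
#'   unadjusted scan's Bonferroni threshold).
#' @return Data frame (probe, class) over the unadjusted hits, with a
#'   `"counts"` attribute (named: remains, explained, unstable).
#' @export
classify_adjustment <- function(unadjusted, adjusted,
                                unstable = rep(FALSE, nrow(unadjusted)),
                                threshold = attr(unadjusted, "threshold")) {
  stopifnot(identical(unadjusted$probe, adjusted$probe),
            length(unstable) == nrow(unadjusted))
  hits <- which(unadjusted$significant)
  cls <- ifelse(unstable[hits], "unstable",
                ifelse(!is.na(adjusted$p[hits]) &
                         adjusted$p[hits] < threshold,
                       "remains", "explained"))
  out <- data.frame(probe = unadjusted$probe[hits], class = cls,
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(remains = sum(cls == "remains"),
                           explained = sum(cls == "explained"),
                           unstable = sum(cls == "unstable"))
  out
}

#' Per-CpG stability screen for the ancestry-adjusted ethnicity model
#'
#' Vectorized version of [stability_flag()] across a methylation matrix:
#' per CpG, the ratio of adjusted to unadjusted ethnicity-coefficient
#' standard errors (the design part is shared; only the residual variance
#' is CpG-specific), plus the design VIF of the ethnicity columns.
#'
#' @param m M-value matrix or [meth_matrix()].
#' @param ethnicity Ethnicity factor.
#' @param covariates Covariate matrix.
#' @param ancestry K-1 ancestry columns used in the adjusted design.
#' @param vif_cut,se_ratio_cut Thresholds as in [stability_flag()].
#' @return Logical vector, one per probe.
#' @export
scan_stability <- function(m, ethnicity, covariates = NULL, ancestry,
                           vif_cut = 100, se_ratio_cut = 10) {
  Y <- as_m_matrix(m)
  n <- nrow(Y)
  eth_block <- indicator_columns(droplevels(as.factor(ethnicity)),
                                 "ethnicity")
  X_un <- cbind(`(Intercept)` = rep(1, n), covariates, eth_block)
  X_ad <- cbind(X_un, ancestry)
  q_un <- qr(X_un)
  q_ad <- qr(X_ad)
  if (q_ad$rank < ncol(X_ad)) {
    return(rep(TRUE, ncol(Y)))   # exactly collinear: everything unstable
  }
  d_un <- diag(chol2inv(qr.R(q_un)))[order(q_un$pivot)][
    match(colnames(eth_block), colnames(X_un))]
  d_ad <- diag(chol2inv(qr.R(q_ad)))[order(q_ad$pivot)][
    match(colnames(eth_block), colnames(X_ad))]
  rss_un <- colSums(qr.resid(q_un, Y)^2) / (n - q_un$rank)
  rss_ad <- colSums(qr.resid(q_ad, Y)^2) / (n - q_ad$rank)
  # per CpG: max over ethnicity columns of SE_adj / SE_unadj
  ratio2 <- outer(rss_ad / rss_un, d_ad / d_un)
  flag <- apply(sqrt(ratio2), 1L, max) > se_ratio_cut
  flag | any(design_vif(X_ad, colnames(eth_block)) > vif_cut)
}

#' Test for non-linear ancestry effects
#'
#' Adds a non-linear block in one ancestry component to the linear model —
#' either second- and third-order polynomials (2 df) or a 3-df cubic-spline
#' block (natural-spline basis with interior knots at the 25th/50th/75th
#' ancestry percentiles, orthogonalized against the linear term) — and
#' compares models with and without the block by nested ANOVA. If
#' `ethnicity` is supplied, ethnicity is re-tested with the non-linear
#' block included.
#'
#' @param y Methylation M-values at one CpG.
#' @param ancestry Continuous ancestry proportion (vector).
#' @param covariates Covariate matrix.
#' @param ethnicity Optional ethnicity factor for the re-test.
#' @param method `"spline"` or `"poly"`.
#' @return List: `p_nonlinear`, `df1`, and `p_ethnicity` (NA when
#'   `ethnicity` is not supplied).
#' @export
nonlinearity_test <- function(y, ancestry, covariates = NULL,
                              ethnicity = NULL,
                              method = c("spline", "poly")) {
  method <- match.arg(method)
  stopifnot(is.numeric(ancestry), length(ancestry) == length(y))
  n <- length(y)
  block <- if (method == "poly") {
    cbind(anc2 = ancestry^2, anc3 = ancestry^3)
  } else {
    spline_block(ancestry)
  }
  eth_block <- if (!is.null(ethnicity)) {
    indicator_columns(droplevels(as.factor(ethnicity)), "ethnicity")
  }
  X_lin <- cbind(`(Intercept)` = rep(1, n), covariates, eth_block,
                 ancestry = ancestry)
  res_lin <- omnibus_scan(matrix(y), X_lin, block)
  p_eth <- NA_real_
  if (!is.null(ethnicity)) {
    X_base <- cbind(`(Intercept)` = rep(1, n), covariates,
                    ancestry = ancestry, block)
    p_eth <- omnibus_scan(matrix(y), X_base, eth_block)$p
  }
  list(p_nonlinear = res_lin$p, df1 = res_lin$df1, p_ethnicity = p_eth)
}

# 3-column cubic-spline block: natural-spline basis with interior knots at
# the 25/50/75 ancestry percentiles, orthogonalized against {1, x} and
# reduced to its 3 independent columns
spline_block <- function(x) {
  kn <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
  if (anyDuplicated(kn) || length(unique(x)) < 5L) {
    abort_admix("too few unique ancestry values for spline knots",
                "admixmeth_invalid")
  }
  B <- splines::ns(x, knots = kn)
  Z <- qr.resid(qr(cbind(1, x)), B)
  qz <- qr(Z)
  if (qz$rank < 3L) {
    abort_admix("spline basis collapsed; too few unique ancestry values",
                "admixmeth_invalid")
  }
  out <- Z[, qz$pivot[seq_len(3L)], drop = FALSE]
  colnames(out) <- paste0("spline", 1:3)
  out
}

#' Enrichment of a candidate CpG set among association signals
#'
#' Two complementary tests against a candidate set (e.g. CpGs previously
#' associated with an environmental exposure): (a) a one-sided binomial
#' test of the count of candidates that are nominally significant
#' (p < 0.05) against the background rate `rate0`; (b) the hypergeometric
#' upper tail for the overlap between a hit set and the candidate set
#' within the tested universe.
#'
#' @param hit_set Character vector of hit probe ids.
#' @param candidate_set Character vector of candidate probe ids (must be a
#'   subset of `universe`, non-empty).
#' @param universe All tested probe ids.
#' @param nominal_p_map Named p-value vector covering the universe.
#' @param rate0 Null nominal-significance rate.
#' @param nominal_alpha Nominal significance level.
#' @return List of class `enrichment_result`: `n_candidates`, `n_nominal`,
#'   `nominal_rate`, `binom_p`, `hyper_p`, `bonferroni_within` (count of
#'   candidates below 0.05/n_candidates).
#' @export
enrichment <- function(hit_set, candidate_set, universe, nominal_p_map,
                       rate0 = 0.05, nominal_alpha = 0.05) {
  if (length(candidate_set) == 0L) {
    abort_admix("candidate set is empty", "admixmeth_invalid")
  }
  if (!all(candidate_set %in% universe)) {
    abort_admix("candidate set must be a subset of the universe",
                "admixmeth_invalid")
  }
  p_cand <- nominal_p_map[candidate_set]
  n_cand <- length(candidate_set)
  n_nom <- sum(p_cand < nominal_alpha, na.rm = TRUE)
  binom_p <- stats::binom.test(n_nom, n_cand, p = rate0,
                               alternative = "greater")$p.value
  overlap <- length(intersect(hit_set, candidate_set))
  hyper_p <- stats::phyper(overlap - 1L, length(hit_set),
                           length(universe) - length(hit_set), n_cand,
                           lower.tail = FALSE)
  structure(list(n_candidates = n_cand, n_nominal = n_nom,
                 nominal_rate = n_nom / n_cand, binom_p = binom_p,
                 overlap = overlap, hyper_p = hyper_p,
                 bonferroni_within = sum(p_cand < 0.05 / n_cand,
                                         na.rm = TRUE)),
            class = "enrichment_result")
}

#' Admixture mapping at one CpG
#'
#' Regresses methylation on local-ancestry dosage at the CpG (K-1 columns,
#' reference ancestry dropped): the coefficient for ancestry k is the
#' M-value change per haplotype of ancestry k, convertible to a
#' methylated:unmethylated fold change with [m_to_fold()]. Also reports the
#' (K-1)-df omnibus test of the whole dosage block. Constant dosage columns
#' are dropped; if none vary an informative error is raised.
#'
#' @param y M-values at the CpG.
#' @param dosage Individuals x K local-ancestry dosage matrix at the CpG.
#' @param covariates Covariate matrix.
#' @param ref Reference ancestry dropped from the block.
#' @return List: `effects` (data frame ancestry, beta, se, p per retained
#'   component), `omnibus` (F, df1, df2, p).
#' @export
admixture_map <- function(y, dosage, covariates = NULL, ref = "EUR") {
  stopifnot(is.matrix(dosage), !is.null(colnames(dosage)))
  block <- compositional_columns(dosage, ref = ref)
  v <- apply(block, 2L, stats::var)
  block <- block[, v > 0, drop = FALSE]
  if (ncol(block) == 0L) {
    abort_admix("local-ancestry dosage has no variance at this site",
                "admixmeth_invalid")
  }
  n <- length(y)
  X_red <- cbind(`(Intercept)` = rep(1, n), covariates)
  fit <- fit_ols(y, cbind(X_red, block))
  keep <- colnames(block)
  tstat <- fit$coefficients[keep] / fit$se[keep]
  effects <- data.frame(
    ancestry = keep,
    beta = unname(fit$coefficients[keep]),
    se = unname(fit$se[keep]),
    p = unname(2 * stats::pt(abs(tstat), fit$df, lower.tail = FALSE)),
    stringsAsFactors = FALSE
  )
  omni <- omnibus_scan(matrix(y), X_red, block)
  list(effects = effects,
       omnibus = list(F = omni$F, df1 = omni$df1, df2 = omni$df2,
                      p = omni$p))
}

#' Scan cis SNPs for a variant explaining an admixture-mapping signal
#'
#' Tests every SNP within `window_bp` of the CpG (boundaries inclusive) by
#' additive-dosage regression, ranks them by p-value, and — when local
#' ancestry is supplied — asks whether conditioning on the best SNP
#' abolishes the local-ancestry association (nested ANOVA of the ancestry
#' block given the SNP).
#'
#' @param y M-values at the CpG.
#' @param geno A [genotype_matrix()].
#' @param cpg_pos CpG physical position (bp, 1-based).
#' @param window_bp Window half-width (default 10 kb; Fig-style regional
#'   scans may use 1 Mb).
#' @param covariates Covariate matrix.
#' @param local_dosage Optional individuals x K local-ancestry dosage at
#'   the CpG for the conditional test.
#' @param ref Reference ancestry for the conditional block.
#' @return List: `table` (snp, pos_bp, beta, se, p, ranked by p; empty when
#'   no SNP falls in the window), `conditional` (NULL, or list with
#'   `ancestry_p_unconditional`, `ancestry_p_given_snp`, `best_snp`,
#'   `abolished`).
#' @export
cis_scan <- function(y, geno, cpg_pos, window_bp = 10000,
                     covariates = NULL, local_dosage = NULL, ref = "EUR") {
  stopifnot(inherits(geno, "genotype_matrix"))
  inside <- which(abs(geno$snps$pos_bp - cpg_pos) <= window_bp)
  n <- length(y)
  X_red <- cbind(`(Intercept)` = rep(1, n), covariates)
  rows <- lapply(inside, function(j) {
    g <- geno$dosages[, j]
    if (anyNA(g)) g[is.na(g)] <- mean(g, na.rm = TRUE)
    if (stats::var(g) == 0) return(NULL)
    fit <- fit_ols(y, cbind(X_red, snp = g))
    tstat <- fit$coefficients[["snp"]] / fit$se[["snp"]]
    data.frame(snp = geno$snps$snp[j], pos_bp = geno$snps$pos_bp[j],
               beta = fit$coefficients[["snp"]], se = fit$se[["snp"]],
               p = 2 * stats::pt(abs(tstat), fit$df, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) {
    tab <- data.frame(snp = character(0), pos_bp = integer(0),
                      beta = numeric(0), se = numeric(0), p = numeric(0))
  } else {
    tab <- tab[order(tab$p), , drop = FALSE]
    rownames(tab) <- NULL
  }
  conditional <- NULL
  if (!is.null(local_dosage) && nrow(tab) > 0L) {
    block <- compositional_columns(local_dosage, ref = ref)
    block <- block[, apply(block, 2L, stats::var) > 0, drop = FALSE]
    g_best <- geno$dosages[, tab$snp[1L]]
    if (anyNA(g_best)) g_best[is.na(g_best)] <- mean(g_best, na.rm = TRUE)
    p_unc <- omnibus_scan(matrix(y), X_red, block)$p
    p_cond <- tryCatch(
      omnibus_scan(matrix(y), cbind(X_red, snp = g_best), block)$p,
      error = function(e) NA_real_)
    conditional <- list(ancestry_p_unconditional = p_unc,
                       ancestry_p_given_snp = p_cond,
                       best_snp = tab$snp[1L],
                       abolished = is.na(p_cond) || p_cond > 0.05)
  }
  list(table = tab, conditional = conditional)
}
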