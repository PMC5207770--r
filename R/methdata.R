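# Methylation and genotype data model, QC, and reference-based cell-type
# deconvolution.
#
# Containers are light S3 lists:
#   meth_matrix      samples x probes values (beta or M, tagged), probe map,
#                    optional detection p-values
#   genotype_matrix  samples x SNPs dosages in {0,1,2,NA}, SNP map with
#                    physical (bp, 1-based) and genetic (Morgan) positions
#   cell_reference   cell-types x probes mean M-value profiles

#' Methylation matrix container
#'
#' @param values Numeric samples x probes matrix. Beta-scale values must lie
#'   strictly in (0,1); M-scale values are unrestricted reals.
#' @param probes Data frame with columns `probe`, `chrom`, `pos` (1-based bp);
#'   probe ids must be unique and match `colnames(values)`.
#' @param scale Either `"beta"` or `"M"`.
#' @param detection_p Optional samples x probes matrix of detection p-values
#'   in \[0,1\].
#' @return An object of class `meth_matrix`.
#' @export
meth_matrix <- function(values, probes, scale = c("beta", "M"),
                        detection_p = NULL) {
  scale <- match.arg(scale)
  stopifnot(is.matrix(values), is.data.frame(probes),
            all(c("probe", "chrom", "pos") %in% names(probes)),
            nrow(probes) == ncol(values))
  if (anyDuplicated(probes$probe)) {
    abort_admix("probe ids must be unique", "admixmeth_invalid")
  }
  if (is.null(colnames(values))) colnames(values) <- probes$probe
  stopifnot(identical(colnames(values), as.character(probes$probe)))
  if (scale == "beta" && (any(values <= 0) || any(values >= 1))) {
    abort_admix("beta-scale values must lie strictly in (0, 1)",
                "admixmeth_invalid")
  }
  if (!is.null(detection_p)) {
    stopifnot(identical(dim(detection_p), dim(values)),
              all(detection_p >= 0 & detection_p <= 1))
  }
  structure(list(values = values, probes = probes, scale = scale,
                 detection_p = detection_p),
            class = "meth_matrix")
}

#' @export
print.meth_matrix <- function(x, ...) {
  cat(sprintf("meth_matrix: %d samples x %d probes (%s scale)%s\n",
              nrow(x$values), ncol(x$values), x$scale,
              if (is.null(x$detection_p)) "" else ", detection p present"))
  invisible(x)
}

#' Genotype matrix container
#'
#' @param dosages Samples x SNPs matrix with entries in {0, 1, 2} or `NA`.
#' @param snps Data frame with columns `snp`, `pos_bp` (1-based) and
#'   `pos_gen` (Morgans); positions must be sorted increasing.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dosages, snps) {
  stopifnot(is.matrix(dosages), is.data.frame(snps),
            all(c("snp", "pos_bp", "pos_gen") %in% names(snps)),
            nrow(snps) == ncol(dosages))
  ok <- is.na(dosages) | dosages %in% c(0, 1, 2)
  if (!all(ok)) abort_admix("dosages must be 0/1/2 or NA", "admixmeth_invalid")
  if (is.unsorted(snps$pos_bp) || is.unsorted(snps$pos_gen)) {
    abort_admix("SNP positions must be sorted increasing", "admixmeth_invalid")
  }
  colnames(dosages) <- snps$snp
  structure(list(dosages = dosages, snps = snps), class = "genotype_matrix")
}

#' Cell-type reference profiles
#'
#' @param profiles Cell-types x probes matrix of mean M-values, with cell
#'   types as rownames and probe ids as colnames.
#' @return An object of class `cell_reference`.
#' @export
cell_reference <- function(profiles) {
  stopifnot(is.matrix(profiles), !is.null(rownames(profiles)),
            !is.null(colnames(profiles)), nrow(profiles) >= 2L)
  structure(list(profiles = profiles, cell_types = rownames(profiles)),
            class = "cell_reference")
}

# ---- beta / M conversion ---------------------------------------------------

#' Convert methylation beta values to M-values
#'
#' M = log2(beta / (1 - beta)), the log2 ratio of methylated to unmethylated
#' signal. Base 2 matters: an M difference of d corresponds to a 2^d-fold
#' change in that ratio (see [m_to_fold()]).
#'
#' @param beta Numeric vector/matrix of beta values in (0,1). Values at
#'   exactly 0 or 1 are clipped into (eps, 1-eps) with a warning.
#' @param eps Clipping tolerance for boundary values.
#' @return M-values, same shape as input.
#' @export
beta_to_m <- function(beta, eps = 1e-6) {
  if (any(beta < 0 | beta > 1, na.rm = TRUE)) {
    abort_admix("beta values must lie in [0, 1]", "admixmeth_invalid")
  }
  if (any(beta <= 0 | beta >= 1, na.rm = TRUE)) {
    warning("beta values at 0/1 clipped to (", eps, ", ", 1 - eps, ")")
    beta <- pmin(pmax(beta, eps), 1 - eps)
  }
  log2(beta / (1 - beta))
}

#' Convert M-values back to beta values
#'
#' Exact inverse of [beta_to_m()]: beta = 2^M / (2^M + 1).
#'
#' @param m Numeric vector/matrix of M-values.
#' @return Beta values in (0,1), same shape as input.
#' @export
m_to_beta <- function(m) {
  # logistic in base 2, written to avoid overflow for large |m|
  stats::plogis(m * log(2))
}

# ---- probe QC --------------------------------------------------------------

#' Filter failed probes by detection p-value
#'
#' Drops probes whose detection p-value exceeds `p_cut` in more than
#' `max_fail_frac` of samples; surviving probe order is preserved.
#'
#' @param meth A [meth_matrix()] with detection p-values.
#' @param p_cut Detection p-value above which a probe fails in a sample.
#' @param max_fail_frac Maximum tolerated fraction of failing samples.
#' @return Filtered `meth_matrix`; the removed probe ids are attached as
#'   attribute `"removed"`.
#' @export
filter_probes <- function(meth, p_cut = 0.01, max_fail_frac = 0.01) {
  stopifnot(inherits(meth, "meth_matrix"))
  if (is.null(meth$detection_p)) {
    abort_admix("detection p-values required for probe filtering",
                "admixmeth_invalid")
  }
  fail_frac <- colMeans(meth$detection_p > p_cut)
  keep <- fail_frac <= max_fail_frac
  if (!any(keep)) {
    abort_admix("all probes removed by detection-p filter", "admixmeth_empty")
  }
  out <- meth_matrix(meth$values[, keep, drop = FALSE],
                     meth$probes[keep, , drop = FALSE],
                     scale = meth$scale,
                     detection_p = meth$detection_p[, keep, drop = FALSE])
  attr(out, "removed") <- meth$probes$probe[!keep]
  out
}

# ---- genotype QC -----------------------------------------------------------

#' Hardy-Weinberg exact test p-value
#'
#' Conditional exact test: given the observed minor-allele count, enumerates
#' all heterozygote counts of matching parity, computes their probabilities
#' under Hardy-Weinberg equilibrium, and sums those no more probable than the
#' observed configuration (two-sided, no mid-p correction).
#'
#' @param n_aa,n_ab,n_bb Genotype counts (major hom, het, minor hom).
#' @return Exact p-value in \[0,1\]; monomorphic sites return 1.
#' @export
hwe_exact_p <- function(n_aa, n_ab, n_bb) {
  stopifnot(n_aa >= 0, n_ab >= 0, n_bb >= 0)
  n <- n_aa + n_ab + n_bb
  n_minor <- 2 * n_bb + n_ab
  if (n == 0 || n_minor == 0 || n_minor == 2 * n) return(1)
  if (n_minor > n) n_minor <- 2 * n - n_minor   # fold to minor allele
  # possible heterozygote counts share the parity of the minor-allele count
  hets <- seq(n_minor %% 2, min(n_minor, 2 * n - n_minor), by = 2)
  # log-probability of each het count under HWE, conditional on allele counts
  logp <- lchoose(n, (n_minor - hets) / 2) +
    lchoose(n - (n_minor - hets) / 2, hets) +
    hets * log(2) - lchoose(2 * n, n_minor)
  # normalize (lchoose form above is the unnormalized multinomial kernel)
  logp <- logp - max(logp)
  p <- exp(logp) / sum(exp(logp))
  obs <- min(n_ab, 2 * n - n_ab)  # fold not needed for het count; use n_ab
  p_obs <- p[match(n_ab, hets)]
  sum(p[p <= p_obs + 1e-12])
}

#' Genotype quality control
#'
#' Removes SNPs with missingness above `miss_cut`, then SNPs out of
#' Hardy-Weinberg equilibrium (exact test p below `hwe_cut`) within any
#' group. Groups with fewer than 5 individuals are skipped in the HWE step
#' with a warning.
#'
#' @param geno A [genotype_matrix()].
#' @param group_labels Per-sample group factor (e.g. ethnicity), used so the
#'   HWE test is applied within each population rather than on the admixed
#'   pool.
#' @param miss_cut Maximum tolerated missingness per SNP.
#' @param hwe_cut HWE exact-test p-value threshold.
#' @return Filtered `genotype_matrix` with a `"removal_log"` attribute
#'   (data frame: snp, reason).
#' @export
qc_genotypes <- function(geno, group_labels, miss_cut = 0.05,
                         hwe_cut = 1e-6) {
  stopifnot(inherits(geno, "genotype_matrix"),
            length(group_labels) == nrow(geno$dosages))
  grp <- droplevels(as.factor(group_labels))
  miss <- colMeans(is.na(geno$dosages))
  drop_miss <- miss > miss_cut
  small <- table(grp) < 5L
  if (any(small)) {
    warning("groups skipped in HWE test (<5 individuals): ",
            paste(names(which(small)), collapse = ", "))
  }
  drop_hwe <- rep(FALSE, ncol(geno$dosages))
  for (g in levels(grp)[!small]) {
    d <- geno$dosages[grp == g, , drop = FALSE]
    n_bb <- colSums(d == 2, na.rm = TRUE)
    n_ab <- colSums(d == 1, na.rm = TRUE)
    n_aa <- colSums(d == 0, na.rm = TRUE)
    pvals <- vapply(seq_along(n_aa), function(j) {
      hwe_exact_p(n_aa[j], n_ab[j], n_bb[j])
    }, numeric(1))
    drop_hwe <- drop_hwe | (pvals < hwe_cut)
  }
  drop_hwe <- drop_hwe & !drop_miss
  keep <- !(drop_miss | drop_hwe)
  log <- data.frame(
    snp = geno$snps$snp[!keep],
    reason = c("missingness", "hwe")[1 + drop_hwe[!keep]],
    stringsAsFactors = FALSE
  )
  out <- genotype_matrix(geno$dosages[, keep, drop = FALSE],
                         geno$snps[keep, , drop = FALSE])
  attr(out, "removal_log") <- log
  out
}

# ---- cell-type deconvolution ----------------------------------------------

# Exact solver for min ||x - A p||^2 subject to p >= 0, sum(p) <= 1.
# Dimension (number of cell types) is small, so we enumerate candidate active
# sets: every subset of coordinates pinned at zero, with the sum constraint
# either slack or tight, solve the equality-restricted least-squares problem,
# and keep the feasible candidate with the lowest objective. The constrained
# optimum is the minimizer over the affine hull of its own active face, so it
# always appears among the candidates.
solve_simplex_ls <- function(A, x) {
  k <- ncol(A)
  AtA <- crossprod(A)
  Atx <- crossprod(A, x)
  best <- NULL
  best_obj <- Inf
  for (mask in 0:(2^k - 1)) {
    free <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) == 0)
    if (length(free) == 0L) {
      p <- numeric(k)
      obj <- sum(x^2)
      if (obj < best_obj) { best <- p; best_obj <- obj }
      next
    }
    for (tight in c(FALSE, TRUE)) {
      nf <- length(free)
      if (tight) {
        kkt <- rbind(cbind(AtA[free, free, drop = FALSE], 1),
                     c(rep(1, nf), 0))
        rhs <- c(Atx[free], 1)
      } else {
        kkt <- AtA[free, free, drop = FALSE]
        rhs <- Atx[free]
      }
      sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      p <- numeric(k)
      p[free] <- sol[seq_len(nf)]
      if (any(p < -1e-9) || sum(p) > 1 + 1e-9) next
      p <- pmax(p, 0)
      r <- x - A %*% p
      obj <- sum(r^2)
      if (obj < best_obj - 1e-12) { best <- p; best_obj <- obj }
    }
  }
  list(p = best, rss = best_obj)
}

#' Estimate leukocyte proportions by constrained projection
#'
#' Reference-based deconvolution: for each sample, finds the cell-type
#' mixture `p` minimizing the squared distance between the sample's M-values
#' and the mixed reference profile, subject to nonnegativity and a
#' sum-to-at-most-one constraint (the slack absorbs unmodeled cell types).
#'
#' @param meth A [meth_matrix()] on the M scale (beta input is converted).
#' @param ref A [cell_reference()]; probes are intersected with `meth`.
#' @return List with `proportions` (samples x cell-types matrix) and
#'   `residual_norm` (per-sample root residual sum of squares).
#' @export
estimate_cell_proportions <- function(meth, ref) {
  stopifnot(inherits(meth, "meth_matrix"), inherits(ref, "cell_reference"))
  shared <- intersect(colnames(meth$values), colnames(ref$profiles))
  if (length(shared) < nrow(ref$profiles)) {
    abort_admix("need at least as many shared probes as cell types",
                "admixmeth_invalid")
  }
  A <- t(ref$profiles[, shared, drop = FALSE])     # probes x cell types
  qa <- qr(A)
  if (qa$rank < ncol(A)) {
    dep <- colnames(A)[qa$pivot[(qa$rank + 1):ncol(A)]]
    abort_admix(paste("reference profiles are collinear:",
                      paste(dep, collapse = ", ")), "admixmeth_collinear")
  }
  vals <- meth$values[, shared, drop = FALSE]
  if (meth$scale == "beta") vals <- beta_to_m(vals)
  fits <- apply(vals, 1L, function(x) solve_simplex_ls(A, x))
  props <- t(vapply(fits, `[[`, numeric(ncol(A)), "p"))
  colnames(props) <- rownames(ref$profiles)
  rownames(props) <- rownames(meth$values)
  list(proportions = props,
       residual_norm = sqrt(vapply(fits, `[[`, numeric(1), "rss")))
}
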