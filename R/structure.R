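# Global methylation structure (principal coordinates of the Euclidean
# distance matrix), genotype PCA for fine-scale structure, PC-factor
# association, and residualization of methylation on a covariate block.

# deterministic sign convention: orient each column so its entry of largest
# magnitude is positive
orient_columns <- function(x) {
  for (j in seq_len(ncol(x))) {
    i <- which.max(abs(x[, j]))
    if (x[i, j] < 0) x[, j] <- -x[, j]
  }
  x
}

#' Principal coordinates of a methylation matrix
#'
#' Classical multidimensional scaling: Euclidean distances between samples,
#' Gower double-centering of -D^2/2, eigendecomposition, coordinates scaled
#' by the square root of the eigenvalues (delegated to [stats::cmdscale()]).
#' For Euclidean input this equals PCA of the row-centered matrix up to
#' column sign; negative eigenvalues (numerically possible) are clipped at
#' zero with a warning.
#'
#' @param m Samples x probes matrix of M-values.
#' @param k Number of coordinates (default 10; truncated to the available
#'   rank with a warning).
#' @return List of class `pcoa_result`: `coordinates` (samples x k,
#'   column-centered, sign-oriented) and `eigenvalues` (nonincreasing,
#'   nonnegative; full spectrum as attribute `"all_eigenvalues"`).
#' @export
pcoa <- function(m, k = 10) {
  stopifnot(is.matrix(m), nrow(m) >= 2L)
  if (k > nrow(m) - 1L) {
    warning("k exceeds available rank; truncated to n - 1")
    k <- nrow(m) - 1L
  }
  d <- stats::dist(m)
  fit <- stats::cmdscale(d, k = k, eig = TRUE)
  if (any(fit$eig < -1e-8 * max(abs(fit$eig)))) {
    warning("negative eigenvalues clipped at 0")
  }
  eig <- pmax(fit$eig, 0)
  coords <- fit$points
  # cmdscale can return fewer columns than requested when trailing
  # eigenvalues are ~0; pad with zeros to the requested k
  if (ncol(coords) < k) {
    coords <- cbind(coords, matrix(0, nrow(coords), k - ncol(coords)))
  }
  coords <- orient_columns(coords)
  colnames(coords) <- paste0("PC", seq_len(k))
  rownames(coords) <- rownames(m)
  structure(list(coordinates = coords,
                 eigenvalues = sort(eig, decreasing = TRUE)[seq_len(k)]),
            class = "pcoa_result",
            all_eigenvalues = sort(eig, decreasing = TRUE))
}

#' Genotype principal components
#'
#' Mean-imputes missing dosages, centers each SNP at twice its estimated
#' allele frequency and scales by the binomial standard deviation
#' `sqrt(2 p (1 - p))`, then takes the top-`k` left singular vectors.
#' Monomorphic SNPs are dropped (logged in the `"dropped"` attribute).
#'
#' @param geno A [genotype_matrix()].
#' @param k Number of components.
#' @return List: `scores` (samples x k, sign-oriented), `eigenvalues`
#'   (squared singular values / (n - 1), nonincreasing), `dropped`
#'   (monomorphic SNP ids).
#' @export
genotype_pca <- function(geno, k = 10) {
  stopifnot(inherits(geno, "genotype_matrix"))
  X <- geno$dosages
  # mean imputation per SNP
  if (anyNA(X)) {
    mu <- colMeans(X, na.rm = TRUE)
    idx <- which(is.na(X), arr.ind = TRUE)
    X[idx] <- mu[idx[, 2L]]
  }
  p_hat <- colMeans(X) / 2
  poly <- p_hat > 0 & p_hat < 1
  dropped <- geno$snps$snp[!poly]
  X <- X[, poly, drop = FALSE]
  p_hat <- p_hat[poly]
  X <- sweep(X, 2L, 2 * p_hat, "-")
  X <- sweep(X, 2L, sqrt(2 * p_hat * (1 - p_hat)), "/")
  k <- min(k, nrow(X) - 1L, ncol(X))
  sv <- svd(X, nu = k, nv = 0)
  scores <- orient_columns(sv$u %*% diag(sv$d[seq_len(k)], k, k))
  colnames(scores) <- paste0("PC", seq_len(k))
  rownames(scores) <- rownames(geno$dosages)
  list(scores = scores,
       eigenvalues = sv$d[seq_len(k)]^2 / (nrow(X) - 1L),
       dropped = dropped)
}

#' Omnibus association between principal coordinates and a predictor
#'
#' For each PC column, compares the covariate-only model with the model
#' adding the predictor block (factor indicators or K-1 compositional
#' columns) by nested ANOVA, returning the omnibus F-test p-value.
#'
#' @param scores Samples x PCs matrix.
#' @param predictor Either a factor (indicator-coded, reference dropped) or
#'   a numeric matrix whose columns enter as-is (pass K-1 columns of a
#'   compositional predictor via [compositional_columns()]).
#' @param covariates Optional numeric design matrix of adjustment columns
#'   (no intercept; one is added).
#' @return Data frame: pc, F, df1, df2, p, stable. Rank-deficient designs
#'   get `stable = FALSE` and `NA` statistics.
#' @export
associate_pc <- function(scores, predictor, covariates = NULL) {
  stopifnot(is.matrix(scores))
  if (is.null(colnames(scores))) {
    colnames(scores) <- paste0("PC", seq_len(ncol(scores)))
  }
  n <- nrow(scores)
  block <- if (is.numeric(predictor) && !is.matrix(predictor)) {
    matrix(predictor, ncol = 1L, dimnames = list(NULL, "predictor"))
  } else if (is.matrix(predictor)) {
    predictor
  } else {
    indicator_columns(predictor, prefix = "group")
  }
  if (!is.null(covariates)) {
    covariates <- as.matrix(covariates)
    # constant covariates are absorbed by the intercept; drop them so the
    # test is invariant to their presence
    covariates <- covariates[, apply(covariates, 2L, stats::var) > 0,
                             drop = FALSE]
  }
  X_red <- cbind(`(Intercept)` = rep(1, n), covariates)
  X_full <- cbind(X_red, block)
  out <- lapply(seq_len(ncol(scores)), function(j) {
    fit_full <- tryCatch(fit_ols(scores[, j], X_full),
                         error = function(e) NULL)
    if (is.null(fit_full)) {
      return(data.frame(pc = colnames(scores)[j], F = NA_real_,
                        df1 = NA_integer_, df2 = NA_integer_, p = NA_real_,
                        stable = FALSE))
    }
    fit_red <- fit_ols(scores[, j], X_red)
    nt <- nested_anova(fit_full, fit_red)
    data.frame(pc = colnames(scores)[j], F = nt$F, df1 = nt$df1,
               df2 = nt$df2, p = nt$p, stable = TRUE)
  })
  do.call(rbind, out)
}

#' Residualize a matrix on a covariate block
#'
#' Column-wise OLS residuals of `m` on the block (plus intercept);
#' residuals are orthogonal to the block. Used to recompute principal
#' coordinates after removing ancestry-driven variation.
#'
#' @param m Samples x features matrix.
#' @param block Numeric covariate matrix (no intercept; one is added).
#' @return Residual matrix of the same shape.
#' @export
residualize <- function(m, block) {
  stopifnot(is.matrix(m))
  X <- cbind(`(Intercept)` = rep(1, nrow(m)), block)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    abort_admix("covariate block is rank deficient", "admixmeth_rank")
  }
  qr.resid(qx, m)
}
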