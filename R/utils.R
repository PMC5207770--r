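#' @keywords internal
"_PACKAGE"

# Shared small helpers. Everything stochastic in the package takes an explicit
# `seed` argument and routes it through `with_seed()` so that repeated calls
# with the same seed are bit-identical and calls with seed = NULL leave the
# caller's RNG stream untouched except for the draws actually consumed.

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  expr
}

#' Draw from a Dirichlet distribution
#'
#' Samples via the standard gamma-ratio construction: independent
#' Gamma(alpha_k, 1) draws normalized to the simplex.
#'
#' @param n Number of draws.
#' @param alpha Positive concentration vector (length K).
#' @return An `n` x `K` matrix; each row is nonnegative and sums to 1.
#' @export
rdirichlet <- function(n, alpha) {
  if (any(!is.finite(alpha)) || any(alpha <= 0)) {
    stop("Dirichlet parameters must be strictly positive", call. = FALSE)
  }
  k <- length(alpha)
  g <- matrix(stats::rgamma(n * k, shape = rep(alpha, each = n)), nrow = n)
  g / rowSums(g)
}

# fail with a consistent message prefix
abort_admix <- function(msg, class) {
  cond <- structure(
    class = c(class, "admixmeth_error", "error", "condition"),
    list(message = msg, call = NULL)
  )
  stop(cond)
}

#' k-1 indicator coding for a factor
#'
#' Drop-one indicator columns (reference = first level), the coding used
#' for categorical predictors throughout the omnibus tests.
#'
#' @param f Factor (or coercible).
#' @param prefix Column-name prefix.
#' @return Numeric matrix with `nlevels(f) - 1` columns.
#' @export
indicator_columns <- function(f, prefix = deparse(substitute(f))) {
  f <- droplevels(as.factor(f))
  if (nlevels(f) < 2L) {
    return(matrix(numeric(0), nrow = length(f), ncol = 0L))
  }
  m <- stats::model.matrix(~f)[, -1L, drop = FALSE]
  colnames(m) <- paste0(prefix, levels(f)[-1L])
  rownames(m) <- NULL
  m
}

#' k-1 columns of a compositional predictor
#'
#' Drops the reference component of a matrix whose rows sum to a constant
#' (ancestry proportions, cell proportions), so the remaining columns are
#' linearly independent of the intercept.
#'
#' @param p Numeric matrix with named columns, rows on a simplex.
#' @param ref Reference component to drop (default: European ancestry by
#'   convention where present, else the first column).
#' @return `p` without the reference column.
#' @export
compositional_columns <- function(p, ref = colnames(p)[1L]) {
  stopifnot(is.matrix(p), !is.null(colnames(p)), ref %in% colnames(p))
  p[, setdiff(colnames(p), ref), drop = FALSE]
}
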