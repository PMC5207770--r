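# Shared fixture builders. Everything is generated in code at test time;
# sizes are kept small so the whole suite stays fast.

# a small but realistic study used by several modules
tiny_study <- function(seed = 42, n_mex = 60, n_pr = 50, ...) {
  simulate_study(profiles = default_profiles(n_mex, n_pr),
                 n_snps = 60, n_cpgs = 80, n_meqtl = 6, n_theta = 12,
                 n_env = 12, n_signature = 12, seed = seed, ...)
}

# plain intercept + one covariate design
design_with <- function(..., n) {
  cbind(`(Intercept)` = rep(1, n), ...)
}

# independent HWE oracle: full enumeration of heterozygote counts using
# the hypergeometric-style conditional distribution computed from scratch
# with exact factorials (no shared code with hwe_exact_p)
hwe_oracle <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  na <- 2 * n_aa + n_ab  # allele A count
  nb <- 2 * n_bb + n_ab
  if (na == 0 || nb == 0) return(1)
  hets <- seq(nb %% 2, min(na, nb), by = 2)
  prob <- vapply(hets, function(h) {
    nbb <- (nb - h) / 2
    naa <- n - h - nbb
    if (naa < 0 || nbb < 0) return(0)
    exp(lfactorial(n) - lfactorial(naa) - lfactorial(h) - lfactorial(nbb) +
          h * log(2) + lfactorial(na) + lfactorial(nb) -
          lfactorial(2 * n))
  }, numeric(1))
  prob <- prob / sum(prob)
  sum(prob[prob <= prob[match(n_ab, hets)] + 1e-12])
}
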