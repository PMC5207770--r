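---
title: "Decomposing ethnicity-associated methylation: models, simulator, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing ethnicity-associated methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(admixmeth)
```

## What the package models

Whole-blood DNA methylation in a three-way admixed cohort (African,
European, Native American ancestry) measured across ethnic sub-groups.
The scientific object is a decomposition: how much of the methylation
difference between self-identified ethnic groups is carried by genetic
ancestry — global proportions, local (cis) haplotype ancestry, fine-scale
structure — and how much remains as a residual ethnicity effect,
interpretable as environmental and social exposure differences.

All modeling is done on M-values, the base-2 logit of the beta value.
Base 2 is load-bearing: an M-difference of `d` is a `2^d`-fold change in
the methylated:unmethylated signal ratio, so effect sizes convert
directly to fold changes (`m_to_fold()`), e.g. `m_to_fold(2.7)` is
`r round(m_to_fold(2.7), 1)`-fold.

The inference engine is deliberately single: every omnibus test — the
ethnicity scan, the ancestry scan, the non-linearity screen, the PC
associations, the conditional cis tests — is the nested-ANOVA F
comparison of two least-squares fits. Likelihood-ratio phrasings of the
same comparison are asymptotically equivalent for Gaussian models, and
one engine means one set of numerical conventions to validate.

Categorical predictors enter as k−1 indicators; compositional predictors
(ancestry proportions, cell proportions) enter as k−1 columns with a
reference component dropped — European ancestry and granulocytes by
convention, since those are the largest components. The choice of
reference changes individual coefficients but not any omnibus F, PVE or
classification.

## The synthetic cohort

The simulator is first-class: it defines the study conditions under
which every downstream claim is tested.

* **Groups.** Four ethnic groups with Dirichlet-distributed global
  ancestry. Means are anchored to the observed median three-way
  ancestries of the large Latino sub-groups (Mexican ≈ 4.3/40.5/55.4
  AFR/EUR/NAM, Puerto Rican ≈ 22.8/65.7/11.2, with smaller Mixed and
  Other groups intermediate), concentration 30 per group. The
  intermediate groups matter statistically, not just cosmetically: with
  only the two large groups, the ethnicity indicator is nearly collinear
  with Native American ancestry and the ancestry-adjusted ethnicity test
  loses most of its power; the four-group cohort restores
  identifiability, as in the real sampling design this emulates.
* **Local ancestry.** Per haplotype, a Markov model: switch points are a
  Poisson process with rate G per Morgan (default G = 8 generations
  since admixture) and the state after each switch is drawn afresh from
  the individual's own proportions q. Same-state switches are allowed
  and tracts are not merged, which makes q exactly stationary and keeps
  the switch-count distribution exactly Poisson — both used as test
  oracles. One diploid genome is two independent haplotypes on a single
  synthetic chromosome, default 2 Morgans with a linear 1 cM/Mb map.
* **Genotypes.** 200 SNPs with Balding–Nichols allele frequencies
  (differentiation 0.15) around a uniform ancestral frequency; each
  haplotype's allele is Bernoulli in the frequency of its local ancestry
  at the SNP. Optionally a fixed-difference "Duffy-null-like" SNP
  (frequency 1 in the African panel, 0 elsewhere) is placed 212 bp from
  a target CpG, reproducing the locus geometry where genotype, local
  ancestry and methylation are almost perfectly coupled.
* **Methylation.** For each CpG, `M = mu + cells'δ + g·β + q'θ +
  env(group) + batch(plate) + ε`, returned on the beta scale. Disjoint
  CpG sets carry cis-meQTL effects (default 1.35 M per allele), global
  ancestry effects, environmental group shifts (default 0.5 M), and
  strong cell-type signature effects (so reference-based deconvolution
  has informative probes); the rest are null. Residual sd defaults to
  0.45 M — the scale at which a 0.5 M group shift is comfortably but not
  trivially detectable at n ≈ 500. Detection-p failures are injected at
  a 0.2% probe rate to exercise QC.
* **Effect parameterization.** Ancestry-mediated effects are specified
  by the ethnic-group contrast they induce: θ on the anchor component
  (Native American) equals the target Mexican–Puerto Rican M-value
  contrast divided by the groups' mean ancestry difference. This puts
  mediated and environmental effects on the same observable scale, so
  classification accuracy compares like with like.

The published study this design emulates analysed real data and reports
no generative parameters; every simulator default above is therefore a
package choice, made once on realism grounds, not fitted to any result.

What the generator does **not** emulate: linkage disequilibrium within
ancestral populations (only ancestry-induced LD exists), probe
cross-reactivity and SNP-under-probe artifacts, normalization batch
structure beyond a plate intercept, sex chromosomes, and read-level
noise. Passing tests therefore demonstrate correctness of the
statistical machinery under the stated model, not robustness to those
real-data pathologies.

## Quality control and deconvolution

Probes fail when their detection p exceeds 0.01 in more than 1% of
samples (the platform vendor's recommendation is qualitative; these are
the configurable defaults). SNPs are dropped at >5% missingness, then at
Hardy–Weinberg exact-test p < 1e-6 *within each ethnic group* — testing
within groups avoids flagging admixture-induced departures
(Wahlund effect). The HWE test is the conditional exact test over
heterozygote counts, no mid-p correction; groups under 5 individuals are
skipped with a warning.

Cell proportions are estimated by constrained projection: per sample,
minimize the squared distance to the mixed reference profile subject to
nonnegativity and a sum-at-most-one constraint (the slack absorbs
unmodeled cell types). Because the number of cell types is small, the
quadratic program is solved exactly by enumerating active sets — every
subset of zeroed components, sum constraint tight or slack — and keeping
the feasible candidate with the lowest objective. This is exact on
noiseless mixtures (a test oracle) and has no tuning parameters.

## Structure, stability, and screens

Principal coordinates are classical scaling of the Euclidean M-value
distances (Gower double-centering, eigendecomposition, coordinates
scaled by the root eigenvalue) — identical to PCA scores of the centered
matrix for Euclidean input, which is asserted as an oracle test.
Numerically negative eigenvalues are clipped at zero with a warning.
Every coordinate and PC is oriented so its largest-magnitude entry is
positive, making runs deterministic. Genotype PCA centers each SNP at
2p̂ and scales by √(2p̂(1−p̂)); monomorphic SNPs are dropped and logged;
fine-structure adjustment uses PCs 3–10 by default, because the leading
two PCs are essentially collinear with the ancestry proportions
themselves.

The stability screen flags CpGs where adding ancestry inflates any
ethnicity-coefficient standard error by more than 10-fold, or where an
ethnicity design column has VIF above 100. Both thresholds are package
choices (the phenomenon they guard against — ethnicity nearly a linear
function of ancestry in-sample — is qualitative); flagged CpGs are
excluded from classification rather than forced into either class.

The non-linearity screen adds either squared and cubed ancestry (2 df)
or a 3-df cubic-spline block — the natural-spline basis with interior
knots at the 25th/50th/75th ancestry percentiles, orthogonalized against
the linear term so the block contributes exactly 3 columns — and
re-tests ethnicity with the block present. Knot placement at quartiles
is the conventional default; the screen errors when ancestry has too few
unique values to define them.

## Decomposition and mediation

Block PVE is `Var(X_b β̂_b) / Var(y)` with sample variances, computed
from sub-blocks of the *joint* fit. For one standardized predictor this
is the familiar β²·Var(x)/Var(y) (so a Pearson correlation of 0.25
corresponds to 6.25% of variance). Cross-block covariance is assigned
only to the joint term; sub-block PVEs therefore need not sum to the
joint PVE, and the ancestry share (ancestry PVE / joint PVE) is
truncated to [0, 1] for reporting. A marginal-fit variant of the
partition is available by fitting the blocks separately, but the
joint-fit reading is the default because it is the only one where
"ethnicity after accounting for ancestry" has a single coherent meaning.

Mediation uses the product-of-coefficients estimator with quasi-Bayesian
uncertainty: fit the mediator and outcome models by OLS, draw
coefficients from their asymptotic normal distributions (default 1000
draws), and report percentile intervals and the two-sided simulation p
for the indirect effect. The normal-approximation default (rather than
bootstrap) keeps runs fast and exactly seed-reproducible; in the linear
no-interaction case ACME + ADE equals the total effect identically. The
treatment contrast defaults to the two largest ethnic groups; the
proportion mediated is reported truncated to [0, 1] with the raw value
retained.

## Numerical conventions and degenerate inputs

* Beta values exactly 0 or 1 are clipped to ±1e-6 with a warning before
  the logit; `m_to_beta()` uses the overflow-safe logistic.
* Rank-deficient designs are an error naming the dependent columns;
  near-deficient designs (above the QR tolerance) flow to the VIF-based
  stability flag instead.
* Constant covariate columns are dropped where they would collide with
  the intercept (PC association, mediation after subsetting).
* Local-ancestry interpolation is in genetic distance, ties toward the
  left SNP; queries outside the SNP range take the nearest SNP's dosage;
  disagreeing flanks give the distance-weighted fractional dosage, which
  downstream regressions treat as continuous. The behaviour at
  disagreeing flanks is a package decision — the underlying inference
  tools leave it undefined.
* All stochastic stages take an explicit seed; two runs with the same
  configuration and seed are byte-identical, including the pipeline's
  JSON report.

## Problem sizes

The default study is 573 individuals (276/220/16/61 by group), 500 CpGs,
200 SNPs on a 2-Morgan chromosome — large enough that the Bonferroni
machinery, the classification and the partitions behave as they would
genome-wide, small enough that the full workflow and test suite run in
seconds to minutes on one CPU. Null-calibration checks use 2000
simulated null CpGs at n = 200; mediation recovery uses 200 replicates
at n = 500; classification recovery uses 300 affected CpGs at n = 500.

## Known limitations

Real headline counts from population cohorts are not reproducible here
by construction: they require the original cohort's data. The pipeline's
claims are therefore about machinery — calibration under the null,
recovery of known architectures, and the self-contained printed
arithmetic — not about re-deriving cohort-specific hit counts. Local
ancestry is consumed as truth from the simulator; inferring it from
genotypes (HMM deconvolution) is out of scope, as are FDR procedures
(the multiple-testing regime is Bonferroni throughout), mixed-model
kinship correction, and treatment–mediator interaction models.
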