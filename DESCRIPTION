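Package: admixmeth
Title: Decomposing Ethnic Differences in DNA Methylation into Ancestry and
    Environmental Components
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline for epigenome-wide studies in
    admixed cohorts. Generates three-way admixed individuals (African,
    European, Native American) with Markov local-ancestry tracts,
    ancestry-differentiated genotypes, and methylation driven by cell
    composition, cis meQTLs, global ancestry, ethnicity-specific environment
    and batch. Provides probe and genotype quality control, beta/M-value
    conversion, reference-based cell-type deconvolution, principal-coordinate
    and genotype principal-component structure analysis, nested-ANOVA omnibus
    EWAS of ethnicity and global ancestry, classification of ethnicity hits
    into ancestry-explained versus residual, variance partitioning of
    methylation into ethnicity, global-ancestry, fine-structure and
    local-ancestry blocks, quasi-Bayesian causal mediation, admixture mapping
    with conditional cis-SNP scans, and enrichment against exposure-associated
    CpG sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    MASS,
    vcfR,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
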