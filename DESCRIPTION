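Package: methmediate
Title: Methylation-Mediated Genetic Effects on Binary Traits via Two-Sample
    Mendelian Randomization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying CpG methylation sites that
    mediate genetic effects on a dichotomized trait from reduced
    representation bisulfite sequencing (RRBS) count data. Implements
    count-based epigenome-wide association testing with covariate and
    methylation principal-component adjustment, cis/trans methylation
    quantitative trait locus (mQTL) mapping with per-class Bonferroni
    correction, two-sample Mendelian randomization (Wald ratio, IVW, Egger,
    weighted median, maximum likelihood) with FDR mediator selection and
    reverse-direction two-stage least squares, the HEIDI heterogeneity test
    separating a shared causal variant from linkage, annotation-aware
    Bayesian fine-mapping by exhaustive enumeration of causal
    configurations, and permutation-based annotation enrichment. A seeded
    synthetic-cohort generator produces genotypes with block LD structure,
    RRBS-style methylation counts, extreme-phenotype cohorts and an
    independent outcome GWAS under mediation, linkage, pleiotropy, reverse
    causation or null generative models.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mvtnorm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
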