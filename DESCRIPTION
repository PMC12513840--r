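Package: metabogen
Title: Genome-Metabolome Association Mapping Across the Allele Frequency Spectrum
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end toolkit for metabolite quantitative trait locus (mQTL)
    studies: medication-corrected association scans, fixed-effect trans-stratum
    meta-analysis with Cochran heterogeneity tests, regional clumping and
    Wakefield approximate-Bayes-factor fine-mapping with 95% credible sets and
    joint-model concordance filters, five-mode molecular pleiotropy
    classification with EFO-based phenotypic pleiotropy, machine-learning
    effector-gene scoring, rare-variant mask/burden testing with Cauchy
    combination and polygenic-score robustness checks, allelic-series
    convergence, and level-versus-locus causal integration through Mendelian
    randomization and colocalization. A built-in synthetic cohort generator
    with planted genetic effects makes every stage testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    randomForest,
    pROC,
    jsonlite,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
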