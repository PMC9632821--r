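Package: crosstraitr
Title: Cross-Trait GWAS Meta-Analysis, Genetic Correlation, Colocalization
    and Fine-Mapping from Summary Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparing the genetic architecture of two complex
    traits from GWAS summary statistics alone: allele/strand harmonization of
    summary-statistics pairs, fixed-effect inverse-variance cross-trait
    meta-analysis including a sign-reversed mode powered for loci with
    opposing directions of effect, genome-wide genetic correlation by LD
    score regression, local heritability and genetic covariance from
    LD-eigendecomposition quadratic forms, approximate-Bayes-factor
    colocalization with a composite two-prior decision rule, and approximate
    stepwise conditional/joint fine-mapping from marginal effects plus a
    reference LD panel. Includes an LD-blocked two-trait summary-statistics
    simulator with planted shared, opposing and trait-specific causal
    variants so every stage can be exercised and calibrated end-to-end
    without external cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor,
    vcfR
Config/testthat/edition: 3
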