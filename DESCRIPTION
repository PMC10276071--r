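Package: targetmr
Title: Drug-Target Mendelian Randomization with Colocalization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-sample drug-target Mendelian randomization for GWAS summary
    statistics: cis-instrument selection around drug-target gene regions
    (FDR filtering, LD clumping, palindrome admissibility, proxy lookup,
    instrument-strength F statistics), exposure/outcome allele harmonization,
    causal-effect estimation (Wald ratio, fixed-effect IVW, MR-Egger, weighted
    median, weighted mode) with odds-ratio scaling and Bonferroni gating,
    positive-control direction gates, and approximate-Bayes-factor
    colocalization of regional association signals. Includes a generator of
    synthetic two-sample GWAS summary statistics with linkage-disequilibrium
    structure for calibration and testing, and a pipeline orchestrating the
    full per-drug-class analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor
Config/testthat/edition: 3
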