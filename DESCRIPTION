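Package: mrflow
Title: Two-Sample Mendelian Randomization from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for two-sample Mendelian randomization on
    GWAS summary statistics: instrument selection (genome-wide significance
    filtering, greedy LD clumping, F-statistic screening), allele
    harmonization with palindromic-variant handling, causal-effect
    estimation (Wald ratio, fixed- and multiplicative random-effects
    inverse-variance weighting, MR-Egger, weighted median, penalized IVW),
    and sensitivity analysis (Cochran's and Ruecker's Q, Egger intercept
    test, MR-PRESSO outlier detection, leave-one-out, funnel-plot tables).
    Includes a seeded synthetic summary-statistics generator with known
    causal structure so every stage is verifiable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
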