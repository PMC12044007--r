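Package: locusfunnel
Title: From GWAS Association Signal to Functional Variant and Target Gene
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, seedable re-implementation of the statistical funnel that
    takes a case-control GWAS locus to a candidate functional variant and target
    gene mechanism: fixed-effect inverse-variance meta-analysis of study-level
    odds ratios; fine-mapping by chi-squared likelihood ratios, LD r-squared
    filtering and a sum-of-single-effects Bayesian credible-set engine;
    allele-differential transcription-factor motif scoring with exact PWM
    p-values by dynamic programming; enumeration-based colocalization of GWAS
    and eQTL signals via approximate Bayes factors; spectral-count IP-MS
    substrate triage with dose-response cross-referencing; a quartile-contrast
    negative-binomial "in silico knockdown" differential-expression analysis
    with preranked gene-set enrichment; and quantification of allelic wet-lab
    assays (qPCR standard curves, percent input, TaqMan allelic ratios,
    luciferase normalization, growth curves). A synthetic-data module generates
    every input with ground-truth labels so the whole pipeline is testable
    without controlled-access data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    Biostrings
Config/testthat/edition: 3
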