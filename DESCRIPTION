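Package: metadeg
Title: Metastasis-Associated Gene Discovery from Multi-Site Tumor RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for discovering metastasis-associated genes
    from bulk RNA-seq of matched primary and metastatic tumors. Implements
    negative-binomial Wald differential expression with median-of-ratios
    normalization, a cascade of tissue-of-origin control filters with an
    opposing-direction rule, a per-patient pairwise concordance filter,
    strand-aware regulatory-window construction with transcription-factor
    binding-site enrichment (one-tailed Fisher tests), and prognostic
    screening by third-quartile expression stratification with Kaplan-Meier
    log-rank tests and multivariate Cox regression. A synthetic cohort
    generator emulating an autopsy cohort of metastatic castration-resistant
    prostate cancer (patient random effects, tissue-specific expression,
    planted differential and prognostic effects) makes every stage testable
    without access to controlled patient data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    S4Vectors,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
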