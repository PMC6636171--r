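Package: methsig
Title: Blood DNA Methylation Episignatures for Genetically Defined Subgroups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derivation and evaluation of blood DNA methylation episignatures
    for genetically defined disease subgroups on Illumina 450K/EPIC-style
    beta-value data. Implements probe quality-control filtering, batch
    mean-centering, variance filtering, reference-based blood cell-type
    deconvolution, per-CpG differential methylation testing (empirical-Bayes
    moderated regression intersected with Mann-Whitney U tests and an
    effect-size threshold), bootstrap bump-hunting detection of differentially
    methylated regions, median-reference correlation classification of
    independent test samples, and hypergeometric feature-enrichment and
    gene-set overlap analyses. A synthetic-data module generates 450K-like
    manifests, cohorts with planted effects, and purified cell-type references
    so the full pipeline is testable end to end.
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
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    limma,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
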