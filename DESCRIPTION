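Package: calremodel
Title: Calcium Remodeling Analysis in Colorectal Cancer Cells
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for studying the remodeling of intracellular
    calcium homeostasis in colorectal cancer cells and its reversal by
    polyamine-synthesis inhibition (DFMO). Extracts resting calcium, store
    content, and store-operated calcium entry (SOCE) features from single-cell
    fura-2 ratio traces; compares experimental conditions with linear mixed
    models (day and coverslip random effects), Box-Cox transformation, Tukey
    pairwise contrasts, and compact letter displays derived from maximal
    cliques; calls differential expression with gene-wise factorial linear
    models, empirical-Bayes moderated t-statistics, and Benjamini-Hochberg
    FDR; combines two expression platforms with a sign-concordance rule and
    classifies treatment-induced reversals over a curated calcium-transport
    gene panel; performs qPCR delta-delta-Ct quantification and sample-level
    transcriptomic quality control. Ships seeded synthetic-data generators
    with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    MASS,
    lme4,
    lmerTest,
    lmtest,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    emmeans,
    limma,
    igraph,
    jsonlite,
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
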