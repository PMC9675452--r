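Package: amnioseq
Title: Amniotic Fluid and Fetal Tissue Transcriptome Maturity Analysis
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for staged-gestation corticosteroid bulk
    RNA-seq cohorts with matched amniotic fluid, lung and hippocampus
    samples. Provides preprocessing (sex-linked gene purge with a
    two-year consistency rule, ANOVA-simultaneous-component batch
    correction that preserves the treatment factor), moderated
    differential expression via limma with blocked designs and
    aggregate FDR, an RNA maturity model that scores organ maturation
    by projection onto an oriented first principal component and
    transfers across tissues, marker-based signature construction and
    nonnegative sum-to-one deconvolution, marker-set Z scores,
    overrepresentation and preranked gene-set enrichment statistics,
    partial Spearman association with a lung-compliance endpoint, and
    Dunnett many-to-one comparisons. A seeded synthetic-cohort
    generator reproduces the study design for parameter-recovery
    testing.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    limma,
    fgsea,
    car,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
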