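Package: lncDiscover
Title: Discovery of Stimulus-Modulated, Interferon-Associated Long
    Non-Coding RNAs from RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A guilt-by-association pipeline for long non-coding RNAs
    (lncRNAs) in innate-immune transcriptomics. From gene-level read
    counts of a stimulation time course it identifies significantly
    modulated lncRNAs with simplified negative-binomial Wald and
    likelihood-ratio tests, classifies their induction kinetics (early,
    early-transient, late) by K-means on z-scored profiles, links them
    to interferon/antiviral protein-coding genes by Spearman
    correlation plus a cis genomic-window filter, replicates candidates
    in case/control cohorts through differential expression and an
    interferon signature score, and nominates putative target genes by
    intersecting query-gene modules of signed weighted co-expression
    networks built on two datasets. A seeded synthetic-data generator
    with a ground-truth record supports calibration and recovery
    testing of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    MASS,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
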