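Package: eisakit
Title: Exon-Intron Split Analysis and Companion Statistics for Total RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Separates transcriptional from post-transcriptional gene regulation
    in total RNA-seq experiments by exon-intron split analysis (EISA): exonic and
    intronic read counting against gene models, negative-binomial generalized
    linear models with Wald and likelihood-ratio tests (including cross-model
    interaction designs), an exon/intron ratio proxy for relative mRNA half-life,
    competitive gene-set enrichment with inter-gene-correlation correction and
    barcode-plot data, hypergeometric overlap tests, and interaction linear
    models plus random-intercept mixed models for metabolite panels. Ships
    synthetic-data generators with known ground truth for every planted effect so
    the whole pipeline is testable without external data, and a config-driven
    pipeline runner with provenance manifests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.2)
Imports:
    stats,
    utils,
    tools,
    methods,
    yaml,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    rtracklayer,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    limma,
    lme4
Config/testthat/edition: 3
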