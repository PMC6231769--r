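Package: wormcis
Title: Mapping and Annotation of Accessible Chromatin Elements Across
    C. elegans Development and Ageing
Version: 0.9.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Identifies focal accessible chromatin sites from ATAC-seq
    coverage by smoothed-second-derivative concavity detection with
    irreproducible-discovery-rate (IDR) filtering, annotates each site as a
    coding/pseudogene promoter, non-coding RNA site, unassigned promoter,
    putative enhancer or other element from stranded capped-RNA 5'-end
    evidence (jump and incr elongation tests, initiation reproducibility,
    outron-aware gene linking), clusters regulated promoter accessibility
    over developmental and ageing time courses with PAM k-medoids, and
    computes tissue-bias and transcription-factor binding enrichments with
    HOT-region masking. A synthetic-data module generates toy genomes and
    signal tracks with planted ground truth so the full pipeline can be
    exercised and validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    stats,
    utils,
    methods,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr,
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
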