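Package: lncstar
Title: Integrated lncRNA, Poly(A)-Site, and Small-RNA Profiling for
    Nutrient-Starvation Transcriptomes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for integrating strand-specific transcriptome assemblies
    with 3'-end (2P-Seq), small-RNA, and degradome sequencing in plants.
    Implements stepwise discovery of putative long non-coding RNAs from
    reference-annotation-based assemblies with dual-reference coding-potential
    classification (RLC/RHC), poly(A)-site peak calling and alternative
    polyadenylation detection from 3'-tag data, FPKM/RP40M normalisation with
    fold-change and tissue-concordance profiling, penalty-scored
    degradome-supported miRNA target calling, and strand-resolved attribution
    of small-RNA signal at cis-natural antisense transcript pairs. Ships a
    seeded synthetic-data generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    methods,
    rtracklayer,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
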