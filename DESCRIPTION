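Package: mosaicstage
Title: Staging and Characterization of Low-Level Somatic Mosaicism from
    Multi-Tissue Deep Sequencing
Version: 0.1.0
Authors@R:
    person("Mosaicstage", "Developers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and stage low-level somatic mosaicism from
    deep multi-tissue read-count data. Implements reciprocal all-pairs
    somatic candidate calling with an exact binomial presence test,
    artifact filtering (read-orientation oxoG filter and BED blacklist
    cascade), classification of variants into early (multi-organ shared),
    late (organ-restricted) and tumor stages, 96-channel mutational
    signature analysis (de novo NMF extraction, non-negative least-squares
    refitting, transcriptional strand asymmetry, exposure clustering), and
    selection statistics (maximum-likelihood dN/dS, context mutability,
    pLI profiles). Includes a fully seeded synthetic cohort generator so
    the entire pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    IRanges,
    GenomicRanges,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    VariantAnnotation,
    SummarizedExperiment,
    withr
Config/testthat/edition: 3
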