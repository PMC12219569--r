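Package: regshift
Title: Regulatory Shift Inference from Chromatin Accessibility, Expression
    and GWAS Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor regulators of a stimulus-driven
    expression response from chromatin accessibility data, and links them to
    disease genetics. Implements distance-decay regulatory-potential scoring
    of transposase cut-count tracks, in-silico deletion of binding sites with
    an expression-matched empirical null, bias-corrected motif footprinting
    with dynamic-binding-site calling, rank-rank hypergeometric overlap of
    expression signatures, and LD-aware prioritization of GWAS variants that
    fall in dynamic binding sites. A seeded synthetic-data generator emulates
    the statistical structure of the real inputs (Poisson cut counts with
    peak enrichment and footprint depletion, planted regulator-target
    effects, LD-block haplotypes) so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    GenomeInfoDb,
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
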