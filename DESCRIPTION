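Package: cassex
Title: Comparative Analysis of Cassette-Exon Responses to Splicing Modulators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for deciphering which cassette exons respond to a
    splicing-modulator compound by comparative transcriptomics between two
    species. Extracts annotated exon-skipping events from gene models,
    quantifies percent spliced in (psi) and treatment-induced delta-psi from
    splice-junction read counts with anchor filtering and RPK30M
    normalisation, classifies per-event responses, pairs cassette exons with
    their best homologous exons in a second species by local alignment,
    scores sequence features (splice sites, exonic splicing
    enhancers/silencers, branch point, polypyrimidine tract), and runs the
    downstream inference: four-way feature comparisons, a nine-category
    cross-species conservation table, a set-overlap independence test, and a
    48-bin hypergeometric enrichment analysis. A synthetic two-species data
    generator with ground-truth sensitivity labels makes the whole pipeline
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicAlignments,
    jsonlite,
    rtracklayer,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
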