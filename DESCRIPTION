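Package: erodeome
Title: Reference-Guided Quantification of Genome Degeneration in Endosymbionts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying reductive genome evolution in host-restricted
    bacteria against a free-living reference. Provides reference-guided gene
    status classification (candidate open-reading-frame enumeration around the
    reference start, Levenshtein edit-distance scoring, size normalisation, and
    two-component normal-mixture expectation-maximisation to separate intact
    genes from pseudogenes), assembly of gene calls into a genes-by-lineages
    retention matrix with universal/fractional categorisation, pathway
    completeness evaluation with host complementation, and a contingency engine
    for retention patterns (Shannon string entropy filtering, exhaustive
    pairwise Hamming distances, a relationship-strength score, and
    radius-bounded clustering of co-retained and reciprocally retained genes).
    A forward simulator of genome degeneration (AT-biased substitution, gene
    inactivation followed by erosion of pseudogenes via deletion, essential /
    operon / redundant-pair constraints) generates ground-truthed synthetic
    data so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    rtracklayer,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
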