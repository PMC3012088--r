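Package: mnasebias
Title: Sequence Bias of MNase Digestion in Nucleosome Positioning Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates micrococcal nuclease (MNase) digestion of naked DNA
    with its strong A/T cutting preference, size selection of a 140-170 bp
    band and single-end sequencing, and implements the track-level analyses
    used to study the resulting bias in nucleosome positioning data:
    normalized per-base coverage maps built by fixed read extension,
    windowed GC-content tracks, GC-frequency profiles aligned at read
    starts, genome-wide average coverage per k-mer, and track correlation,
    density-grid and region-report comparisons. Includes a synthetic genome
    generator with controllable base composition (poly-A/T tracts, GC-rich
    elements) so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
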