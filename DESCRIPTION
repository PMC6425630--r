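Package: maptig
Title: Linkage-Map-Guided Cleaning of Long-Read Overlap Graphs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Anchors long sequencing reads to a dense genetic linkage map by
    colouring each read with the map bins it spans, builds a bidirected
    read-overlap graph from all-vs-all mappings, propagates colours to
    unmapped reads, removes colour-inconsistent edges, and extracts guided
    (rainbow-path) unitigs.  Includes a synthetic-data generator (random
    multi-chromosome genome, dense linkage map, long reads with known
    origins, true alignments, and true suffix-prefix overlaps with injected
    spurious ones) and evaluation utilities that classify read colourings
    and graph edges against the simulation truth.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
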