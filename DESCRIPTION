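Package: readstore
Title: Network-Accessible Column Store for Genome-Aligned Read Positions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A compact column-store database for mapped short-read positions
    with a sparse block index giving O(log n + m) genomic interval queries.
    Stores per-chromosome sorted hit positions, packed strand/length, and
    per-hit weights in parallel binary column files; supports paired-end
    read sets via dual-keyed duplication, server-side count/weight-sum
    aggregates and histograms at caller-chosen bin widths, a line-oriented
    text query protocol served over TCP, a matching client library, SAM/BAM
    and BED importers, and a deterministic synthetic-data generator.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    GenomicAlignments,
    Rsamtools,
    rtracklayer,
    S4Vectors,
    GenomeInfoDb,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
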