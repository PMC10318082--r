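Package: baccam
Title: Encoding, Simulation and Decoding of Plate-Based Optogenetic DNA Image Storage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for storing binary 8x12 plate images in DNA via an
    optogenetic Cre-LoxP recorder and retrieving them by sequencing. The
    package encodes text or bitmap payloads onto barcoded 96-well plates,
    simulates the recording and sequencing channel (per-well excision
    fractions, read-depth variation, substitution errors, pooling, serial
    dilution and index-selective re-amplification) emitting FASTQ, and
    decodes pooled reads back into images through dual-index
    demultiplexing, excision-ratio statistics, and an automated
    deconvolution workflow combining local-outlier-factor curation,
    one-dimensional clustering (k-means, DBSCAN, OPTICS, Gaussian mixture),
    full ON/OFF assessment and cluster grouping.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
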