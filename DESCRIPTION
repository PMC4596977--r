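Package: shinglescan
Title: Density-Based Skin Lesion Border Detection with Shingled Partitioning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Detects skin lesion borders in dermoscopy images with a
    grid-adapted DBSCAN using Manhattan-distance neighborhoods. Provides the
    classic serial clustering as a correctness oracle and a partitioned
    redesign that tiles the image into shingles (core tiles plus an
    overlapping lap region), resolves cluster identity per shingle by an
    iterative minimum-pixel-id label negotiation, and merges shingles through
    the doubly-observed overlap with a union-find transitive closure; the two
    routes produce identical labelings. Includes core/border/noise node
    classification, border overlay rendering, XOR-based segmentation metrics
    (border error, precision, recall), seeded synthetic fixtures
    (lesion-like blobs, serpentine worst-case paths, partition-spanning
    clusters), and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    png,
    jsonlite,
    parallel,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
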