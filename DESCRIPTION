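Package: lazyse
Title: Lazy Remote-Backed SummarizedExperiment with HDF REST and SQL Back Ends
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Represents large expression matrices as SummarizedExperiment
    objects whose assay is a lazy, block-readable matrix view over a storage
    seed: an in-memory array, a chunked HDF5 dataset, a minimal HDF REST data
    service, or a relational long-format (triple-store) database. Subsetting
    by feature and sample identifiers, by genomic-range overlap, and by
    sample covariates stays in the familiar metadata-aware idiom while
    numerical values are fetched on demand through a deterministic,
    chunk-aware request planner. Includes a conformant in-process mock of the
    REST dialect with a request log for laziness auditing, a seeded
    negative-binomial fixture generator emulating single-cell and tumor
    cohort designs, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    R6,
    Matrix,
    DBI,
    RSQLite,
    rhdf5,
    curl,
    httpuv,
    optparse,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    DelayedArray,
    processx
Config/testthat/edition: 3
Collate:
    'conditions.R'
    'seeds.R'
    'lazy-matrix.R'
    'planner.R'
    'genomic-ranges.R'
    'core-model.R'
    'export.R'
    'hsds-mock.R'
    'hsds-client.R'
    'sql-backend.R'
    'fixtures.R'
    'backends.R'
    'cli.R'
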