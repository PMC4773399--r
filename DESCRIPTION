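Package: hcstore
Title: Metadata Management for High Content Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A single API over three storage strategies for high content
    screening metadata: a typed object store for the experimental
    containment hierarchy (screen, plate, well, field, image, channel,
    reagent, region of interest), flexible annotations (ordered key-value
    maps with scientific units, namespaced file attachments, tags), and an
    HDF5-backed columnar feature store for analytic output with restricted
    querying and per-row object backlinks. Includes bulk CSV/TSV annotation
    import keyed by well address, token-based text search, group-based data
    permissions, per-plane pixel statistics with windowed thumbnail
    rendering, a seeded synthetic-screen generator, and a command-line
    interface.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.3), methods
Imports: stats, utils, tools, jsonlite, yaml, tiff, png
Suggests: testthat (>= 3.0.0)
SystemRequirements: HDF5 C library (libhdf5)
NeedsCompilation: yes
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
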