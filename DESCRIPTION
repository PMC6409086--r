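Package: dtoolr
Title: Lightweight Data Management with Portable, Verifiable Datasets
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Packages collections of data files together with administrative,
    structural and descriptive metadata into portable, verifiable datasets.
    A dataset carries a checksum manifest that supports fixity checking
    (presence, size and content-hash verification), stable content-addressable
    item identifiers derived from relative paths, free-form YAML descriptive
    metadata and per-item metadata overlays. All reads and writes flow through
    a pluggable storage-broker abstraction so that datasets behave identically
    on a plain directory tree and on an object-store-like backend, and can be
    copied between them without loss. Includes a command-line interface for
    creating, inspecting, copying and verifying datasets and for generating
    inventories of dataset collections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    digest,
    jsonlite,
    uuid,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
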