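Package: barcodeprep
Title: Staging DNA-Barcode Records and Metadata Files for Repository Upload
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools that prepare DNA-barcode specimen records and their
    metadata files (specimen images, AB1 chromatogram traces, FASTA
    sequence files) for upload to centralized repositories such as the
    Barcode of Life Datasystems (BOLD). Provides recursive discovery and
    listing of target files by extension, bulk copying into flat upload
    folders, size-capped partitioning of files into upload packs, copying
    by an explicit name list, and five multiple-sequence FASTA
    transformations: gap removal, length ranking, header- and
    sequence-based dereplication, and multi-line to single-line
    conversion. All outputs follow a deterministic date-stamped naming
    convention, and a seeded fixture generator produces synthetic
    directory trees and FASTA files with known ground truth for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
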