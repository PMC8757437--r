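Package: confmeta
Title: Conformer Ensemble and Metadata Management for SDF Files
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reads and writes MDL SDfiles (V2000 molfiles) together with
    molecule-, conformation- and atom-level metadata, keeping structures and
    data in one queryable ensemble. Provides a small expression language
    ("metastatements") for deriving, slicing and filtering metadata, CSV and
    mol2 (TRIPOS SYBYL atom type) interchange, distance-based filtering of
    docking poses against a binding-site point, plotting (scatter with trend
    line, 1D and 2D histograms), a deterministic generator of docking-style
    fixtures, and a command-line front end.
License: MIT
Encoding: UTF-8
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
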