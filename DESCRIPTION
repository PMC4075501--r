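Package: regkit
Title: Metadata-Driven Patient Registry Engine
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A library and command-line toolkit for building patient
    registries from metadata instead of code. Registry curators define
    reusable data elements (typed fields with validation rules and
    permitted value groups), compose them into forms and sections, and
    capture per-patient records in an isolated schema-less store per
    registry. Derived data elements are computed on read from a
    restricted arithmetic expression grammar, field-level role-based
    access control filters every view, and complete registry
    definitions round-trip through a canonical YAML interchange format
    suitable for version control and sharing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    R6,
    digest,
    jsonlite,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
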