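Package: tmanet
Title: Patient Network Analysis of Tumor-Marker Tissue Microarray Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Clusters cancer patients from immunohistochemical tumor-marker
    staining profiles using a signed weighted correlation network over
    samples, derives mortality groups by average-linkage clustering with an
    adaptive branch cut and eigensample-based module merging, extracts
    compact percentile-threshold prognostic rules by classification tree,
    builds a stepwise Cox comparator rule from optimally dichotomized
    markers, and validates threshold rules on independent expression
    datasets across probe-set combinations. Includes a synthetic-data
    generator emulating tissue-microarray staining distributions, missing
    data, and group-linked censored survival so the full pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    rpart
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite
Config/testthat/edition: 3
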