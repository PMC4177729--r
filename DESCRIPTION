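Package: ragmm
Title: Traffic-Light (RAG) Genetic Risk Stratification for Multiple Myeloma
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Implements a red-amber-green ("RAG") genetic risk
    stratification engine for multiple myeloma. Detected genetic lesions
    (FISH/karyotype cytogenetics and sequencing-derived gene mutations)
    are matched against an editable knowledge base of 22 lesion
    categories, each weighted red (3.0), amber (2.0) or green (1.0); the
    mean weight over matched categories yields a risk score between 1.0
    and 3.0 that maps onto four prognostic bands. The package also derives
    International Staging System (ISS) stage from serum
    beta-2-microglobulin and albumin, flags the ultrahigh-risk
    combination of ISS stage II/III with more than one adverse lesion,
    tracks score trajectories across serial samples, renders a
    weight-proportional circular ("pizza") plot as deterministic SVG,
    generates seeded synthetic cohorts with known ground truth, and ships
    a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    yaml,
    jsonlite,
    VariantAnnotation
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
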