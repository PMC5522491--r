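Package: sdmgap
Title: Species Distribution Modelling and Conservation-Gap Analysis on
    Regular Grids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for pseudo-absence-based habitat
    suitability modelling of the black-necked crane (Grus nigricollis) and
    similar range-restricted species: background-lattice generation,
    ratio-controlled pseudo-absence sampling, class-balanced random-forest
    suitability scoring (relative index of occurrence), threshold selection
    by sensitivity-specificity sum maximization, AUC/TSS evaluation with
    independent testing points, inverse-distance-weighted surfaces,
    human-influence conservation-gap overlay, and buffer-exclusion
    delineation of potential breeding areas.  Includes a virtual-species
    landscape simulator so the whole workflow is testable end to end
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    igraph,
    jsonlite,
    yaml,
    mgcv,
    stats,
    utils
Suggests:
    pROC,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
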