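Package: heterochron
Title: Developmental Tempo Inference from Chimeric Dual-Species RNA-Seq Time Courses
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying developmental-tempo differences (heterochrony)
    between species co-differentiated in chimeric cultures, from species-tagged
    expected-count matrices. Implements dual-species count separation and
    misalignment QC, depth and principal-component replicate outlier filters,
    two-stage size-factor normalization, continuous piecewise-linear (segmented)
    trend regression with automatic breakpoint selection, early-up/early-peak/
    differential-expression gene classification, event-ratio and correlation-based
    acceleration-factor estimation, reference-tissue dissimilarity staging, gene
    set enrichment on timing differences, and a synthetic chimeric time-course
    generator with ground-truth time warps for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    splines,
    Matrix,
    jsonlite,
    yaml,
    scran,
    fgsea
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
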