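Package: splicerhythm
Title: Rhythmicity and Rhythmic Alternative Splicing in Circadian
    Expression Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detection and characterisation of circadian (24-h) and
    ultradian (12-h) rhythms in gene- and transcript-level expression
    time courses. Implements a rank-based umbrella test for rhythmicity,
    robust harmonic (cosinor) regression, calling of phase-shifted
    differentially rhythmic splice-isoform pairs, FIRMA-style
    residual-persistence splicing scores for probe-level array data,
    circular phase statistics with circular k-means clustering, and
    promoter GC/clock-motif enrichment with average-odds PSSM scoring
    against shuffled controls. Ships a synthetic-data generator with
    machine-readable ground truth emulating dense circadian sampling
    designs, and an end-to-end pipeline with per-design threshold
    profiles.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    edgeR,
    limma,
    Biostrings,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
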