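Package: circomics
Title: Circadian Multi-Omics Rhythm Detection and Regulatory Network
    Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for analysing diurnal rhythms across multi-omics
    time courses sampled over two daily cycles: label-free proteomics
    normalization (fraction-of-total and per-cycle z-scores), a
    nonparametric JTK-family rhythmicity test built on Kendall
    concordance with cosine reference templates and an exact null
    distribution, time-phase grouping and phase-specific feature
    selection, nomination of dominant rhythmic transcription factors
    from DNA-binding-activity and target-gene rhythms, and
    correlation, shortest-path and resampling analyses on regulatory
    and protein-interaction networks. Includes a synthetic-data
    generator with planted ground truth for power, calibration and
    recovery studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
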