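Package: paleoNe
Title: Demographic Reconstruction and Breakpoint Dating from Dated
    Sediment-Core Gene Genealogies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for reconstructing historical effective population
    sizes of environmental gene variants archived in dated sediment
    cores, and for dating the onset of demographic change. Includes a
    heterochronous coalescent simulator with time-varying population
    size and GTR+Gamma sequence evolution under a relaxed clock,
    contamination- and occupancy-based variant filters, a grouped
    Bayesian skyline coalescent sampler with calendar-grid posterior
    summaries, a permutation test of phylogeny-deposition-date
    association based on the Association Index, random-forest trend
    modelling with partial dependence, and single-breakpoint segmented
    regression with an exhaustive grid-search oracle. A synthetic
    multi-site study generator with known ground truth makes every
    stage testable by parameter recovery.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    ranger,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    phangorn
Config/testthat/edition: 3
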