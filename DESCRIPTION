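Package: nucensemble
Title: Ensemble Integration of Cross-Platform Nucleosome Positioning Maps
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Integrates multiple genome-wide nucleosome positioning call sets
    into consensus maps of stable and dynamic nucleosomes. Call sets are
    restructured as binary occupancy tracks and combined by logical AND
    (stable consensus), averaged pairwise XOR (dynamic disagreement), and a
    binomial decomposition of the per-site occupancy frequency into
    probability profiles for each agreement level. Downstream analyses cover
    TSS-anchored composite profiles with equilibrium-point detection and
    spacing estimation, per-gene measurability and positioning
    signal-to-noise ratios, promoter-pattern k-means clustering, local
    regulatory correlation (LRC) maps against gene properties, +1-nucleosome
    and TATA-box contrasts, and quantification of nucleosome sliding between
    growth conditions. A synthetic-genome generator emulating phased
    nucleosome arrays sampled by noisy platforms makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    rtracklayer,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Epigenetics, NucleosomePositioning, Coverage, Sequencing
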