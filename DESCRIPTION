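Package: pvdarbor
Title: Quantification of PVD Dendritic Arbor Morphology, Microtubule
    Polarity, and FRAP Kinetics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to quantify the stereotyped menorah-structured dendritic
    arbor of the C. elegans PVD neuron from SWC skeletons: branch-order
    classification (primary through quaternary), anterior-posterior region
    segmentation, per-region branch counts and a normalized branch
    complexity index, penetrance scoring, EB-comet kymograph analysis of
    microtubule polarity, and single-exponential FRAP recovery fitting.
    Includes a synthetic-data module that simulates genotype-specific
    arbors, kymographs, and FRAP traces with known ground truth, and
    from-first-principles implementations of two-way ANOVA with Tukey HSD,
    Welch t-tests, and exact binomial penetrance intervals.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml,
    tiff,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    optparse
Config/testthat/edition: 3
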