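Package: neuritescreen
Title: Morphometric Analysis of High-Content siRNA Neurite Outgrowth Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for high-content morphometric siRNA screens of neuronal
    differentiation. Generates synthetic 384-well screen data (tabular and
    image-level) with known injected effects, measures per-field neurite
    length, neuronal cell-body area and fluorescence totals from channel
    images, normalizes wells against plate positive/negative controls,
    scores growth, differentiation and neurite-outgrowth phenotypes with a
    plate-wise regression-deviation statistic in control standard-deviation
    units, calls hits at a 3-SD threshold with stringency grading, exclusion
    rules and secondary-screen reproduction status, and analyzes combined
    knockdown (epistasis) designs with Dunnett many-to-one comparisons,
    knockdown-phenotype correlations and masked-intensity t-tests.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    EBImage,
    mvtnorm,
    tiff,
    jsonlite,
    yaml,
    ggplot2,
    rlang
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
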