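Package: damsleep
Title: Sleep Scoring, Temperature-Shift Analysis, Fluorescence Traces and
    Intensity-Correlation Colocalization for Drosophila Circuit Studies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis toolkit for Drosophila sleep and memory-circuit
    experiments. Parses Trikinetics Drosophila Activity Monitor (DAM) files,
    scores sleep by the field-standard rule (maximal runs of five or more
    minutes of zero beam crossings), computes sleep architecture in 12-hr
    light/dark windows and 30-min profiles averaged across days, and
    implements the thermogenetic temperature-shift design: per-fly baseline
    subtraction followed by comparison of the experimental genotype against
    both GAL4 and UAS genetic controls, reporting the conservative
    (numerically greatest) Mann-Whitney p value. Also provides ROI
    fluorescence trace analysis (percent delta-F/F, normalized FRET ratios,
    polarity-aware maximum-response extraction, Kruskal-Wallis gated pairwise
    rank tests) and per-pixel product-of-the-differences-from-the-mean (PDM)
    intensity-correlation colocalization maps for two-channel confocal
    stacks. Synthetic-data generators with known ground truth make every
    pipeline stage testable without external recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
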