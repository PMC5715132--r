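Package: perkin
Title: Kinematics and Population Statistics for the Drosophila Proboscis
    Extension Response
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis tools for quantitative proboscis
    extension response (PER) assays in Drosophila. Generates synthetic
    eye-to-proboscis distance traces, rendered two-landmark video frame
    stacks with ground truth, and Bernoulli responder populations; tracks
    landmark pairs through grayscale frame stacks; extracts per-trace
    kinematic features (episode onset, offset, duration, peak extension)
    and a spline-based "extra path" tremor index; and provides the
    population-level statistical layer (exact binomial confidence limits,
    omnibus and pairwise post-hoc chi-square tests with multiplicity
    adjustment, one-way ANOVA with Tukey HSD, and noncentral chi-square
    and noncentral-F power calculations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    graphics,
    splines,
    jsonlite,
    yaml,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
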