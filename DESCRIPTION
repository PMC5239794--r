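Package: curvestats
Title: Constant-Curvature Contour Statistics in Images and Psychophysics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying contours defined by constant curvature, both
    psychophysically and in image statistics. Generates Gabor micro-pattern
    contour-detection stimuli with grid-based density control, simulates
    two-interval forced-choice observers and fits Gaussian orientation-tuning
    functions to their responses, extracts oriented edge elements from
    grayscale images with radial and oriented log-Gabor filters, maps
    four-element constant-curvature contour fragments among the extracted
    edges, and summarizes the orientation statistics of contour end elements.
    A synthetic-image generator with planted edge chains makes every stage of
    the pipeline testable without external image corpora.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite,
    png,
    yaml
Suggests:
    tiff,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
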