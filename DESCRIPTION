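Package: octaline
Title: A-Line-Based Plaque Classification for Intravascular OCT
Version: 0.1.0
Authors@R:
    person("octaline", "maintainers", email = "octaline@example.org",
           role = c("aut", "cre"))
Description: Classifies individual A-lines of polar-domain intravascular
    optical coherence tomography (IVOCT) pullbacks as fibrocalcific,
    fibrolipidic, or other tissue. Provides the full pipeline: dynamic
    programming lumen boundary detection and pixel-shift alignment, a small
    1-D convolutional network and a fully connected baseline trained with
    class-weighted cross-entropy and early stopping, dense conditional
    random field label smoothing with morphological area opening in the
    en-face (theta, z) view, guided backpropagation saliency maps, and
    pullback-held-out cross-validation. A synthetic pullback simulator with
    exact ground truth makes every stage testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
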