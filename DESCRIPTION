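Package: cnfield
Title: Color Neural Field Model of Chromatic Assimilation and Contrast
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates a Wilson-Cowan neural field over cortical space and an
    opponent color space, with a difference-of-Gaussians lateral connectivity
    that is excitatory between nearby hypercolumns tuned to similar colors and
    inhibitory between remote hypercolumns or opponent colors. The steady-state
    activity profile of a hypercolumn (its color sensation) predicts asymmetric
    color-matching experiments as a projection: the matched color is the one
    whose comparison sensation is nearest in sup norm to the test sensation.
    Includes stimulus generators for striped (purple/lime) patterns and
    square-in-surround displays, a SoftMin matching emulator, synthetic
    matching-dataset generation, and derivative-free regression of the model
    parameters to matching data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
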