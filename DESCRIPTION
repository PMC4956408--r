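Package: widefieldpool
Title: Population-Pooling Models and Analysis for Widefield Imaging of Visual Cortex
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Links mesoscopic widefield fluorescence signals (calcium
    indicators such as GCaMP, and voltage-sensitive dyes) to the activity of
    locally pooled V1 neurons. Implements a population-pooling model in which
    each imaged location sums single-neuron responses over scattered contrast
    semi-saturation values, receptive-field centers, and preferred
    orientations, with a power-law spiking nonlinearity separating
    spiking-like from potential-like signals; a synthetic-cortex generator
    (orientation-preference maps with pinwheels, affine retinotopy,
    indicator-specific temporal kernels, multi-trial movies); the standard
    widefield analysis pipeline (blank subtraction, response windows,
    first-harmonic amplitudes, d-prime maps, spatial bandpass, composite
    orientation maps, tuning curves); and least-squares estimation of the two
    free scatter parameters with a parameter-recovery harness.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    graphics,
    yaml,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    knitr,
    rmarkdown
Config/testthat/edition: 3
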