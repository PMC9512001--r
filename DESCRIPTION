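Package: okfluor
Title: Semiautomatic Measurement of Orthokeratology Fluorescein Patterns
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the concentric "bull's eye" fluorescein pattern seen
    under an orthokeratology (reverse-geometry rigid gas-permeable) contact
    lens from a cropped slit-lamp photograph. A deterministic pipeline
    (proportional resize, green-channel extraction, contrast stretch,
    horizontal-meridian band averaging, absolute first derivative, peak
    detection) locates the eight horizontal crossings of the four zone
    boundaries; widths of the central bearing, tear reservoir, mid-peripheral
    bearing and edge-lift zones are derived and calibrated to millimetres
    against the nominal lens diameter. Includes a seeded synthetic-pattern
    generator with exact ground truth, Bland-Altman agreement statistics
    (limits of agreement with approximate and exact noncentral-t confidence
    intervals, paired t, Pearson r) for observer and method comparisons, and
    a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    ggplot2,
    graphics,
    grDevices,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
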