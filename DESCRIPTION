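Package: ladderms
Title: Neutral-Loss Ladder Annotation and DDA Knockout Simulation for
    Herbal Multicomponent LC-MS/MS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rule-based annotation of tandem mass spectra from complex
    herbal extracts: accurate-mass and adduct-aware compound library
    search, depth-first inference of glycosidic neutral-loss ladders,
    diagnostic sapogenin ion classification for saponins and related
    natural product classes, and malonyl/acetyl acylation detection.
    Includes a data-dependent acquisition (DDA) simulator with top-N
    precursor selection and eluate "component knockout" windows, so the
    exposure of minor components shadowed by dominant chromatographic
    peaks can be quantified against a synthetic ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
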