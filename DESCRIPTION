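Package: vasowave
Title: Nocturnal Vasoconstriction Biomarkers from Photoplethysmography Amplitude
Version: 0.1.0
Authors@R:
    person("Vasowave", "Maintainers", email = "maintainers@vasowave.dev",
           role = c("aut", "cre"))
Description: Quantifies nocturnal peripheral vasoconstriction from raw
    photoplethysmography (PPG). Extracts the peak-to-trough pulse amplitude
    (PPGamp), preprocesses it in 15-minute segments (outlier capping,
    percentile normalization, detrending, respiratory low-pass filtering),
    detects vasoconstriction events and computes the Mvasoc event metric and
    the PPGampCV sliding-window coefficient of variation, aligns
    unsynchronized finger and wrist sensors by maximum positive
    cross-correlation within a +/-30 s window, and reproduces within-device
    and across-device correlation validation analyses. Includes a synthetic
    dual-device nocturnal PPG generator with ground-truth events for
    end-to-end testing, CSV and EDF (European Data Format) input/output, and
    a reproducible pipeline runner with a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
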