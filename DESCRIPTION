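Package: egmdur
Title: Automated Electrogram Duration Mapping for Ventricular Tachycardia
    Substrate Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated estimation of intracardiac bipolar electrogram (EGM)
    duration on high-density electroanatomic maps. Implements a sliding
    standard-deviation window transform with percent-of-maximum threshold
    detection of EGM onset and offset, duration-cutoff classification of
    abnormally prolonged electrograms, aggregation of 3-D left-ventricular
    maps onto the AHA 17-segment model, diagnostic-odds-ratio based
    validation of the signal-processing parameters against ablation
    lesion locations, and bull's-eye / 3-D visualization. Includes a
    synthetic-cohort generator with scar architecture and class-specific
    EGM morphologies so the full pipeline is testable without clinical
    data, plus a documented open interchange format (EAMX) for
    electroanatomic map exports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    signal,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
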