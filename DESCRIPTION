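Package: irtbreath
Title: Breathing-Pattern Extraction from Infrared Thermography Video
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating respiration rate in cattle from infrared
    thermography video. Per-frame binary region-of-interest (nostril) masks
    are fused with co-registered thermal frames; in-mask temperatures are
    aggregated per frame by three rival statistics (maximum, mean,
    integrated sum), smoothed with a Gaussian window, and converted to
    breaths per minute via peak detection and the five-breath rule.
    Includes Otsu-style optimal quantization of thermal frames, instance
    detection scoring (IoU, precision, recall, average precision at a fixed
    IoU threshold), a synthetic radiometric scene simulator with ground
    truth for desk-scale validation, and agreement/parameter-recovery
    analyses between true and estimated rates.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    png,
    stats,
    utils,
    zoo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
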