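Package: octprog
Title: Global OCT Metrics and Event-Based Glaucoma Progression on Synthetic Retinal Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and evaluation framework for event-based glaucoma
    progression detection with global optical coherence tomography (OCT)
    summary metrics. Generates ground-truthed longitudinal phantoms of
    widefield retinal nerve fibre layer (RNFL) and macular ganglion cell
    layer plus inner plexiform layer (RGCLP) thickness maps; extracts the
    derived 3.45-mm circumpapillary circle scan and the 6 x 6 mm macular
    window to compute the global averages G_ONH and G_mac; fits
    test-retest event thresholds by quantile regression; classifies
    progression under single-metric, OR, AND and fixed 5-micron rules;
    tabulates false negatives, false positives and accuracy against ground
    truth; and runs sensitivity simulations of the three measurement
    failure mechanisms (local damage, disc/fovea centring error,
    segmentation error), including age-corrected normative deviation maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    graphics,
    grDevices,
    utils,
    jsonlite,
    tiff
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
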