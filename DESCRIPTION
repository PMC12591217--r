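Package: magdrop
Title: Digital Twin of an Electromagnetic Bead-and-Droplet Immunoassay Platform
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulator of an automated magnetic-bead digital-microfluidics
    immunoassay platform. Models a grid of individually addressable electromagnetic
    coils driving a permanent-magnet motor, the force balance separating droplet
    transport from bead extraction across the water-oil interface, the fluidic state
    of a sealed reagent biochip, a protocol compiler that turns assay command scripts
    into timed coil-activation schedules via breadth-first path-finding, a
    phenomenological sandwich-immunoassay chemistry with four-parameter logistic
    calibration and limit-of-detection estimation, a drift-compensated optical
    readout path, and synthetic diagnostic cohorts with rank-based group comparison
    and ROC analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    grDevices,
    graphics,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC
Config/testthat/edition: 3
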