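Package: limbusflow
Title: Episcleral Vessel Morphology and Aqueous Outflow Mapping from
    Confocal Laser Endomicroscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies episcleral blood-vessel morphology and regional
    aqueous-outflow variation from fluorescence confocal laser
    endomicroscopy (CLE) frames. Implements multiscale Gaussian-ridge
    vessel segmentation with scale-derived diameter estimates, ROI
    fluorescence time-course analysis with saturating wash-in fits, and
    circumferential limbal quadrant statistics. Includes a synthetic CLE
    phantom generator with known ground truth (field of view, optical
    resolution, vessel calibre range, wash-in kinetics, and
    quadrant-dependent fluorescence) for validation of the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    minpack.lm,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
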