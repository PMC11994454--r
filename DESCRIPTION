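Package: cslfm
Title: Confocal Scanning Light-Field Microscopy Simulation and Reconstruction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Wave-optics modelling, forward simulation and 3D reconstruction for
    confocal scanning light-field microscopy (csLFM). Provides a scalar Debye
    light-field point-spread-function engine with microlens-array sampling and
    pixel realignment into the spatial-angular domain, a line-confocal
    rolling-shutter modulation model with Airy-unit slit-design calculators
    (photon efficiency, axial coverage, background-suppression energy maps), a
    phantom generator and raw-sensor acquisition simulator, multi-view
    Richardson-Lucy iterative tomography with simplified digital adaptive
    optics, and the evaluation metrics used for intravital imaging
    (signal-to-background ratio, 3D SSIM, Fourier ring correlation, FWHM,
    Calinski-Harabasz score, dF/F trace analysis, spike detection and
    orientation selectivity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tiff,
    yaml,
    jsonlite,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
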