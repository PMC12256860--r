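Package: flickering
Title: Membrane Flickering Spectroscopy and Active Microrheology of Red Blood Cell Contours
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the spontaneous ("flickering") fluctuations of
    the red blood cell equatorial contour: an active Langevin simulator of
    membrane contour dynamics (thermal Helfrich modes plus dichotomous
    cytoskeletal kickers), a ring-image rendering and subpixel contour
    segmentation chain with drift correction, erythrocyte morphotype
    classification by circularity and contourness, real-space flickering
    statistics (local variances, effective temperatures, hot spots, Green-Kubo
    diffusivities), Welch power spectral densities with passive/active
    spectral decomposition, and generalized Stokes-Einstein microrheology with
    fractional Maxwell viscoelastic fitting.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    EBImage,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
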