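Package: parbeam
Title: Parallel-Beam Tomographic Reconstruction and Synthetic Vessel Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for two-dimensional parallel-beam computed tomography:
    analytic ellipse phantoms (the classic Shepp-Logan head phantom and a
    configurable coronary-vessel cross-section with stenosis and calcified or
    noncalcified plaque), exact and discrete Radon forward projectors with
    seeded Gaussian noise, reconstruction by filtered back-projection
    (Ram-Lak and Shepp-Logan ramp filters), direct Fourier inversion via the
    central slice theorem, and a simultaneous iterative technique (SIRT) with
    a matched adjoint projector. Includes image-quality metrics, automated
    lumen-diameter stenosis measurement and grading, plaque detection, and a
    reproducible synthetic cohort experiment producing diagnostic
    sensitivity, specificity and accuracy tables.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    png,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
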