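Package: ritfm
Title: Refractive-Index Traction Force Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Computational core for label-free traction force microscopy on
    refractive-index tomograms. From paired 3D volumes of a bead-seeded elastic
    substrate (relaxed versus under cell traction) the package estimates the 3D
    displacement field by windowed Fourier cross-correlation with subpixel
    refinement, and inverts it into shear (in-plane) and normal (out-of-plane)
    surface tractions via monotone total-variation-regularized FISTA against the
    Boussinesq-Cerruti elastic half-space Green's tensor. Includes a synthetic
    bead-phantom and forward-deformation generator for end-to-end validation,
    3D Gaussian high-pass pre-filtering, masking and global registration,
    TV-regularized volume deconvolution, and dry-mass quantification from
    refractive-index contrast (surface density maps, weight pressure, traction
    statistics, differential tractions and kymographs).
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    graphics,
    jsonlite,
    optparse,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
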