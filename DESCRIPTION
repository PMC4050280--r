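Package: subtomo
Title: Sub-Tomogram Averaging and Model Fitting for Membrane-Anchored Fusogens
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: A tested, reusable pipeline for determining the structure and
    membrane geometry of single-pass fusogens imaged by cryo-electron
    tomography on the surface of vesicles. Provides a ground-truthed
    synthetic tomogram generator (spherical vesicles decorated with
    elongated protein phantoms, Gaussian tilt statistics, hard-core
    packing, a +/-60 degree missing wedge and additive noise), local-minima
    particle picking with membrane-proximity filtering, constrained
    iterative sub-volume alignment and gold-standard even/odd averaging
    with Fourier shell correlation, geometric statistics (tilt to the
    membrane normal, nearest-neighbour spacing, back-plotting,
    volume-thresholded isosurface measurement), rigid-body and
    hinge-restricted flexible fitting of multi-domain atomic models into
    EM density, and emPAI-based relative protein abundance.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tibble,
    rlang,
    ggplot2,
    generics,
    bio3d,
    yaml,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
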