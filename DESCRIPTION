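Package: tnirsim
Title: Coupled Optical-Thermal Dosimetry for Transcranial Near-Infrared Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Chromophore-resolved tissue optics and heat transfer for
    transcranial near-infrared stimulation (tNIRS) dosimetry. Composes
    layer absorption coefficients from chromophore contributions (water,
    lipid, oxy- and deoxyhemoglobin, oxidized and reduced cytochrome c
    oxidase), solves the steady-state diffusion approximation of the
    radiative transfer equation on synthetic four-layer head phantoms
    (combined scalp and skull, cerebrospinal fluid, gray matter, white
    matter), couples the absorbed optical power into the Pennes bioheat
    equation with blood perfusion and convective surface loss, and
    cross-checks the diffusion solver against a weighted-photon voxel
    Monte Carlo transport model. Includes an experiment pipeline for
    multi-wavelength and per-chromophore runs with CSV, JSON and VTK
    output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
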