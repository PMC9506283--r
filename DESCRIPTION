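Package: leafletlab
Title: Mechanics, Rheology, X-Ray Scattering and Trajectory Analysis of
    Lipid Monolayers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for Langmuir monolayer models of the
    erythrocyte inner leaflet: static compression moduli and gradient
    segmentation of surface pressure-area isotherms; surface dilatational
    stress-relaxation rheology (multi-exponential fitting, closed-form
    viscoelastic spectra, Cole-Cole diagnostics, plateau moduli);
    Parratt-type specular X-ray reflectivity slab modelling with
    Nevot-Croce roughness and electron density profile reconstruction;
    grazing-incidence diffraction Bragg-peak fitting with Scherrer
    coherence lengths; and structural operators for monolayer coordinate
    trajectories (periodic Voronoi area per lipid, deuterium order
    parameters, slab thicknesses, electron density profiles, contact and
    hydration maps, hydrogen bonds, radial distribution functions).
    Seeded synthetic generators for every input class make the whole
    pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    minpack.lm,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
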