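Package: memphase
Title: Quantitative Analysis of Lipid Membrane Phase Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis chain for the phase behavior of fusogenic lipid
    membranes. Provides a composite small-angle neutron scattering (SANS)
    forward model combining a body-centered-cubic paracrystal of small
    vesicles, a core-shell vesicle form factor, and a lamellar-stack
    paracrystal, with weighted least-squares fitting and Bragg-peak
    indexing; fluorescence recovery after photobleaching (FRAP) half-time
    and diffusion-coefficient estimation with group comparison; giant
    unilamellar vesicle (GUV) membrane detection by circular Hough
    transform with angular intensity profiling and bright-domain
    detection; static 31P chemical-shift-anisotropy powder lineshape
    simulation and non-negative mixture decomposition; and seeded
    synthetic-data generators for all modalities.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    minpack.lm,
    pracma,
    png,
    stats,
    tiff,
    utils,
    withr
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
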