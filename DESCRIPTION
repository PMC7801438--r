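Package: hydrokin
Title: Confined Water Diffusion Kinetics and Super-Arrhenius Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing the temperature dependence of water dynamics in
    enzyme channels. Estimates self-diffusion coefficients from particle
    trajectories via ensemble mean-squared displacements, fits temperature-indexed
    rate or diffusion series to Arrhenius and deformed (super-)Arrhenius laws with
    a temperature-dependent activation energy, characterises protein channel
    hydration (water counts, centerline geometry, hydropathy), and provides seeded
    synthetic trajectory and rate generators with known ground truth so every
    analysis stage is testable without molecular-dynamics output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
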