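Package: chiralmelt
Title: Ternary Melting Phase Diagrams for Diastereomeric Salt Resolution Screening
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts the likely success of optical resolutions by fractional
    crystallization of diastereomeric salts from a handful of DSC measurements.
    Builds binary and ternary equilibrium melting phase diagrams under
    ideal-eutectic assumptions using the Schroeder-van Laar and Prigogine-Defay
    liquidus equations, locates binary and ternary eutectic points, maps the
    dominating-solid domains of the composition triangle, and computes
    resolvability metrics (eutectic composition, Fogassy resolubility parameter,
    melting-point-gap and double-salt verdict rules). Ships the thermodynamic
    data of three worked chloromandelic-acid resolution systems and a seeded
    generator of synthetic ideal-eutectic systems for property testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
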