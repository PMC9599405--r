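Package: gradink
Title: Gradient Formation in Single-Cartridge Extrusion Bioprinting
Version: 0.1.0
Authors@R:
    person("Gradink", "Developers", email = "gradink@example.org",
           role = c("aut", "cre"))
Description: Reduced-order simulation and analysis of concentration gradient
    formation when two hydrogel blocks (an AB block system) are extruded from a
    single printer cartridge. Implements Ostwald-de Waele power-law rheology
    (evaluation and flow-curve fitting), a quasi-steady axisymmetric velocity
    field for the barrel and conical tip under free-slip or no-slip walls,
    Lagrangian interface-marker advection with an independent upwind
    finite-volume cross-check, mapping of outlet concentration time series onto
    printed-strand arc length, gradient profile metrics (transition midpoint,
    10-90% width, monotonicity, plateau detection, core-shell statistics), an
    inner-filter fluorescence response model, and seeded synthetic-data
    generators for flow curves and strand fluorescence sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
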