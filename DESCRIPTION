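Package: mosscalib
Title: Isomer-Shift Calibration for 57Fe Mossbauer Spectroscopy from
    Sphere-Integrated Electron Densities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts 57Fe Mossbauer isomer shifts from the electron density
    integrated inside a small sphere centered on the iron nucleus. Provides an
    analytic Gaussian-type-orbital density and Laplacian engine with Molden and
    Gaussian-cube readers, a Gauss-Legendre x Lebedev sphere quadrature for the
    sphere-integrated density descriptor, a curated 103-signal experimental
    calibration dataset of iron complexes, ordinary-least-squares calibration
    with leave-one-out cross-validation and sphere-radius sweeps, and electric
    field gradient to quadrupole-splitting conversion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    pracma,
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
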