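Package: silkbls
Title: Elastic Anisotropy of Silk Fibers from Brillouin Light Scattering
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for Brillouin light scattering (BLS)
    measurements of elastic anisotropy in protein fibers such as Bombyx
    mori silkworm silk and Nephila spider dragline silk. Computes probed
    phonon wave vectors for transmission, reflection and backscattering
    geometries, extracts phonon peaks from BLS spectra by Lorentzian
    least-squares fitting, converts frequency shifts to angle-dependent
    sound velocities, inverts the Christoffel equation for the
    transversely isotropic stiffness tensor by weighted nonlinear least
    squares, and converts stiffness constants to engineering moduli
    (Young's moduli, shear moduli, bulk modulus, Poisson's ratios).
    Includes a synthetic-data generator emulating Lorentzian doublet
    spectra with counting noise and Christoffel-model velocity datasets,
    so every pipeline stage is testable without instrument data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
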