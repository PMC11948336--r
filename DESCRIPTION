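Package: cavos
Title: Ellipsoidal-Cavity Field Corrections for Computed Oscillator Strengths
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Corrects computed molecular oscillator strengths for the local
    (cavity) electromagnetic field experienced by a solute in a continuum
    dielectric solvent. Fits an ellipsoid to van der Waals / PCM surface
    points, evaluates depolarization factors by the ellipsoidal elliptic
    integral, forms orientation-averaged cavity-field correction factors for
    transition dipole moment components, derives experimental oscillator
    strengths and mean band energies from digitized extinction spectra, and
    benchmarks computed against experimental strengths with exact-band-limit
    and improved-fit assignment modes, agreement statistics, and iterative
    L1-optimal scaling factors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    pracma,
    stats,
    utils
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
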