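Package: spincascade
Title: Femtosecond X-Ray Spectroscopy Analysis of Photoinduced Spin Cascades in Heme Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for femtosecond pump-probe X-ray emission
    (Fe K-alpha, K-beta) and X-ray absorption (Fe K-edge XANES) spectroscopy
    of photoexcited metalloproteins. Provides asymmetric pseudo-Voigt
    line-shape fitting of the K-alpha doublet with numeric FWHM extraction,
    construction and window integration of laser-on minus laser-off transient
    spectra, spin-state fingerprinting against reference difference spectra,
    closed-form Gaussian-IRF-convolved multiexponential kinetic fitting with
    residual-resampling bootstrap confidence intervals and small-sample
    information-criterion model comparison, sequential spin-cascade
    population models, Beer-Lambert photoexcitation-yield accounting, and a
    synthetic-data generator emulating the spectral and kinetic structure of
    a low-spin to intermediate-spin to high-spin relaxation cascade in a
    ferric heme.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    pracma,
    yaml
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
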