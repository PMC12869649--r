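Package: radiacoustics
Title: Quantitative Radiacoustic Dosimetry with a Physics-Informed Enhancement Network
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital-twin toolkit for quantitative radiacoustic dosimetry.
    Generates synthetic proton pencil-beam and FLASH-electron dose volumes,
    converts absorbed dose to initial acoustic pressure through the Grueneisen
    relation, propagates the pressure field with a k-space pseudospectral wave
    solver, and models the full detection chain (radiation pulse profile,
    finite transducer apertures with sub-element summation, damped-oscillator
    impulse response) as a unified linear forward operator. Reconstructs
    initial pressure from limited-view sinograms by time reversal, enhances
    the reconstruction with a compact convolutional network trained under a
    dual image-domain and sinogram-domain loss whose physics term
    back-propagates through the exact adjoint of the embedded forward
    operator, calibrates relative pressure to absolute dose with a
    single-point factor, and evaluates results with gamma-index, SSIM and
    PSNR dosimetric metrics.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, yaml, jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
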