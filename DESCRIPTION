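Package: depotr
Title: Quantifying Drug Depot Permeation in Tissue from Time-Lapse X-Ray Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how an injected drug solution permeates
    subcutaneous and muscle tissue, from time-lapse 2D X-ray radiographs of
    the growing depot. Implements flat-field correction and Beer-Lambert
    inversion of radiograph stacks, drift registration, wetting-front
    tracking with injection/diffusion-region labelling, relative
    solution-content (RCS) profiles and their temporal variation,
    region-of-interest coefficient-of-variation analysis, cube-root depot
    growth fitting, Darcy point-source permeability estimation, tissue
    resistance pressure and fracture-toughness criteria, and a synthetic
    radiograph generator with full ground truth for validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
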