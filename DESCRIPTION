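Package: rosetrace
Title: UV-B and PAR Interception on 3D Rosette Canopies with Downstream
    Phenolic and Fluorescence Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Monte-Carlo forward ray tracing of photosynthetically active
    (PAR, 400-700 nm) and ultraviolet (UV, 280-400 nm) radiation
    interception on triangle-mesh plant canopies inside LED growth
    chambers, together with the downstream quantitative toolchain used in
    controlled-environment UV-B supplementation studies: parametric
    generation of spiral-phyllotaxis rosette meshes, Lambertian LED
    emitter models with virtual-sensor power calibration, biologically
    effective UV dosimetry with action-spectrum weighting,
    chlorophyll-fluorescence quenching analysis (Fv/Fm, PhiPSII, NPQ),
    colorimetric assay arithmetic (total flavonoids, total phenolics,
    DPPH radical scavenging), and standardized multiple regression
    separating the effects of intercepted UV dose from leaf developmental
    age on per-leaf biochemistry.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
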