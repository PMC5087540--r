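Package: gvfsnakes
Title: Weak-Edge-Preserving Gradient Vector Flow Snakes
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Parametric active-contour (snake) segmentation with gradient
    vector flow external force fields. Provides the classical GVF field,
    the generalized (GGVF), normal (NGVF) and normally biased (NBGVF)
    variants, and a convex-coefficient field whose normal/tangent diffusion
    weights depend on edge-map intensity, protecting weak edges while
    smoothing noise. Ships synthetic benchmark phantoms (disk, square,
    U-shape, long thin indentation), salt-pepper and multiplicative noise
    models, a semi-implicit snake evolver, polygon rasterization and
    precision/recall/F1 segmentation scoring.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    png,
    purrr,
    rlang,
    tibble,
    tiff,
    yaml
Suggests:
    jsonlite,
    optparse,
    pracma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
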