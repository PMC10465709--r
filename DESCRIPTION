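Package: fibrilpfc
Title: Phase-Field Crystal Modeling of Collagen Fibril Self-Assembly
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the extracellular self-assembly of collagen fibrils in
    embryonic tendon as a crystallization process, using a conserved
    phase-field crystal (PFC) model solved with a stabilized semi-implicit
    pseudospectral scheme on periodic rectangles and on irregular
    inter-cellular-space domains (smoothed-boundary method). Includes
    Gaussian-random-field initial conditions, scalar observables (free
    energy, protomer availability, crystallized fraction), fibril-center
    detection, Delaunay-triangulation defect analysis (5/7 disclinations,
    defect proportion, edge-length and neighbor-count distributions),
    parameter sweeps over the destabilization strength and mean phase field,
    seeded synthetic-data generators for domain masks, planted-defect
    lattices and developmental protein-abundance time series, and the
    complete-case log2 fold-change normalization used for such time series.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deldir,
    dplyr,
    EBImage,
    generics,
    ggplot2,
    graphics,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
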