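Package: firepatchr
Title: Fire Patch Reconstruction and Morphological Functional Traits from
    Burn-Date Rasters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs individual fire patches from per-pixel burn-date
    rasters with a temporally constrained flood-fill (queen connectivity,
    day-difference cut-off), computes per-patch morphological functional
    traits (perimeter, core area, shape index, fractal correlation
    dimension, standard deviation ellipse), and aggregates catalogues to
    1-degree gridded products including a Poisson-weighted power-law fit of
    the fire-size distribution. Ships a synthetic fire generator with known
    ground truth so the whole pipeline is testable without satellite data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    ncdf4,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
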