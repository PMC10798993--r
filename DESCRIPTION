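Package: lufor
Title: Mapping Land Use Following Deforestation with Active-Learning Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for mapping land use following
    deforestation from high-resolution multispectral imagery. Provides a
    seeded synthetic-scene generator emulating 4-band (blue, green, red,
    nir) mosaics with 15 land-use classes, forest-loss masks with loss
    years, and realistically corrupted reference annotations; vegetation
    index computation (NDVI, SAVI, NDMI) and minimum-area loss-patch
    filtering; a compact attention U-Net trained with focal loss,
    implemented from scratch on BLAS matrix operations; entropy-driven
    pool-based active learning with a simulated annotator; confusion-matrix
    metrics (per-class F1, macro/micro F1, user's and producer's accuracy);
    stratified good-practices estimation of map accuracy and class areas
    with standard errors per five-year period; and kernel-density hotspot
    grids with lustrum/region trend tables.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    withr,
    yaml
Suggests:
    EBImage,
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
LinkingTo:
    Rcpp
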