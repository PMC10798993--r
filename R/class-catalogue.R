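#' Land-use class catalogue
#'
#' The fifteen land-use-following-deforestation classes used throughout the
#' pipeline, together with the spectral and geometric parameters the synthetic
#' scene generator uses to emulate them. Band means are reflectances in
#' \[0, 1\] for the four mosaic bands (blue, green, red, nir); `band_sd` is the
#' per-pixel Gaussian noise level around the class mean; `geometry_kind`
#' controls the shape family the generator paints for the class.
#'
#' Class spectra are chosen so that vegetation classes sit high in nir, built
#' surfaces (roads, settlement, mining) are bright across the visible bands,
#' and water is dark in nir: the standard qualitative structure of optical
#' land-cover signatures. All pairwise spectral distances are large relative
#' to the default noise so the mapping problem is solvable (see the
#' separability property in the package tests).
#'
#' @param band_sd Per-class spectral noise standard deviation (reflectance
#'   units). One value recycled to all classes, or a length-15 vector.
#' @return A tibble with columns `class_id` (0-based integer code), `name`,
#'   `blue`, `green`, `red`, `nir`, `band_sd`, `geometry_kind`.
#' @export
#' @examples
#' default_classes()
default_classes <- function(band_sd = 0.02) {
  cls <- tibble::tribble(
    ~class_id, ~name,                        ~blue, ~green, ~red, ~nir, ~geometry_kind,
    0L, "small-scale cropland",        0.10, 0.24, 0.22, 0.46, "field",
    1L, "large-scale cropland",        0.16, 0.32, 0.32, 0.58, "field",
    2L, "pasture",                     0.08, 0.34, 0.18, 0.64, "blob",
    3L, "mining",                      0.32, 0.36, 0.44, 0.34, "blob",
    4L, "roads",                       0.40, 0.44, 0.48, 0.52, "polyline",
    5L, "other-land with tree cover",  0.05, 0.18, 0.10, 0.74, "texture",
    6L, "plantation forest",           0.03, 0.13, 0.05, 0.88, "lattice_plantation",
    7L, "coffee",                      0.08, 0.24, 0.14, 0.60, "lattice_plantation",
    8L, "settlement",                  0.48, 0.50, 0.55, 0.42, "cluster",
    9L, "tea plantation",              0.06, 0.30, 0.09, 0.52, "field",
    10L, "water",                      0.12, 0.14, 0.10, 0.04, "meander",
    11L, "oil palm",                   0.03, 0.20, 0.07, 0.66, "lattice_plantation",
    12L, "rubber",                     0.06, 0.15, 0.13, 0.55, "lattice_plantation",
    13L, "cashew",                     0.11, 0.22, 0.17, 0.70, "lattice_plantation",
    14L, "cacao",                      0.07, 0.11, 0.10, 0.44, "lattice_plantation"
  )
  cls$band_sd <- rep_len(band_sd, nrow(cls))
  validate_classes(cls)
  cls
}

validate_classes <- function(classes) {
  stopifnot(is.data.frame(classes))
  need <- c("class_id", "name", "blue", "green", "red", "nir", "band_sd", "geometry_kind")
  missing <- setdiff(need, names(classes))
  if (length(missing) > 0) {
    stop("class table lacks columns: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(classes$class_id) > 0) stop("class_id values must be unique", call. = FALSE)
  bm <- as.matrix(classes[, c("blue", "green", "red", "nir")])
  if (any(!is.finite(bm)) || any(bm < 0) || any(bm > 1)) {
    stop("band means must lie in [0, 1]", call. = FALSE)
  }
  kinds <- c("field", "lattice_plantation", "polyline", "meander", "blob", "cluster", "texture")
  bad <- setdiff(unique(classes$geometry_kind), kinds)
  if (length(bad) > 0) stop("unknown geometry_kind: ", paste(bad, collapse = ", "), call. = FALSE)
  invisible(classes)
}

#' @rdname default_classes
#' @param classes A class-catalogue tibble.
#' @export
class_band_means <- function(classes) {
  m <- as.matrix(classes[, c("blue", "green", "red", "nir")])
  rownames(m) <- classes$name
  m
}
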