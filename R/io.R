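# Raster and manifest I/O.
#
# Scenes are written as multi-band TIFF (bands blue, green, red, nir as
# 32-bit samples) plus a JSON sidecar holding the geotransform, band names,
# region/country ids and pixel size; masks are single-band 16-bit TIFFs with
# an integer offset so the unlabeled code -1 round-trips exactly.

MASK_OFFSET <- 1L      # stored value = code + offset, so -1 maps to 0
MASK_SCALE <- 65535

mask_to_unit <- function(mask) (mask + MASK_OFFSET) / MASK_SCALE
unit_to_mask <- function(u) as.integer(round(u * MASK_SCALE)) - MASK_OFFSET

write_mask_tiff <- function(mask, path) {
  m <- matrix(mask_to_unit(as.integer(mask)), nrow(mask), ncol(mask))
  tiff::writeTIFF(m, path, bits.per.sample = 16)
  invisible(path)
}

read_mask_tiff <- function(path) {
  m <- tiff::readTIFF(path)
  matrix(unit_to_mask(m), nrow(m), ncol(m))
}

#' Write a scene to disk
#'
#' Writes `<id>_bands.tif` (4 samples per pixel), `<id>_truth.tif`,
#' `<id>_loss.tif`, `<id>_loss_year.tif` (years stored as offsets from 2000)
#' and a JSON sidecar `<id>.json` with the georeferencing metadata.
#'
#' @param scene A `lufor_scene`.
#' @param dir Output directory (created if needed).
#' @param id Scene identifier used as the filename stem.
#' @return The sidecar path, invisibly.
#' @export
write_scene <- function(scene, dir, id = "scene") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tiff::writeTIFF(scene$bands, file.path(dir, paste0(id, "_bands.tif")),
                  bits.per.sample = 16)
  write_mask_tiff(scene$truth_mask, file.path(dir, paste0(id, "_truth.tif")))
  write_mask_tiff(scene$loss_mask * 1L, file.path(dir, paste0(id, "_loss.tif")))
  yr <- scene$loss_year
  yr[yr > 0] <- yr[yr > 0] - 2000L
  write_mask_tiff(yr, file.path(dir, paste0(id, "_loss_year.tif")))
  side <- list(
    id = id, bands = c("blue", "green", "red", "nir"),
    geotransform = scene$geotransform, pixel_size = scene$pixel_size,
    region_id = scene$region_id, country_id = scene$country_id
  )
  path <- file.path(dir, paste0(id, ".json"))
  jsonlite::write_json(side, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scene written by [write_scene()]
#'
#' @param dir Directory containing the files.
#' @param id Filename stem.
#' @return A `lufor_scene` (without the generator config; `classes` must be
#'   reattached by the caller if needed).
#' @export
read_scene <- function(dir, id = "scene") {
  side <- jsonlite::read_json(file.path(dir, paste0(id, ".json")), simplifyVector = TRUE)
  # libtiff flags the 4th (nir) sample as a non-colour channel; harmless here
  bands <- suppressWarnings(tiff::readTIFF(file.path(dir, paste0(id, "_bands.tif"))))
  truth <- read_mask_tiff(file.path(dir, paste0(id, "_truth.tif")))
  loss <- read_mask_tiff(file.path(dir, paste0(id, "_loss.tif"))) == 1L
  yr <- read_mask_tiff(file.path(dir, paste0(id, "_loss_year.tif")))
  yr[yr > 0] <- yr[yr > 0] + 2000L
  structure(list(
    bands = bands, truth_mask = truth, loss_mask = loss, loss_year = yr,
    geotransform = as.list(side$geotransform), pixel_size = side$pixel_size,
    region_id = side$region_id, country_id = side$country_id,
    classes = NULL, config = NULL
  ), class = "lufor_scene")
}

#' Write a pool manifest as CSV
#' @param pools A `lufor_pools` object.
#' @param path Output CSV path.
#' @export
write_manifest <- function(pools, path) {
  write.csv(pools$manifest, path, row.names = FALSE)
  invisible(path)
}

# small non-cryptographic content hash (FNV-1a over the serialized object),
# used to tag artifacts with the configuration they came from
config_hash <- function(x) {
  bytes <- as.integer(serialize(x, NULL, version = 2))
  h <- 2166136261
  for (b in bytes) {
    h <- bitwXor(as.integer(h %% 2^31), b)
    h <- (h * 16777619) %% 2^31
  }
  sprintf("%08x", as.integer(h))
}
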