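#' Normalize raw bands to \[0, 1\]
#'
#' Two modes. `"fixed"` (default) assumes the input is already expressed as
#' reflectance in \[0, 1\] and only clips numerical excursions. `"minmax"`
#' rescales each band to \[0, 1\] by its own per-scene minimum and maximum,
#' which is the natural choice for digital-number mosaics assembled from
#' heterogeneous sensors; a constant band maps to all zeros.
#'
#' @param bands H x W x 4 numeric array (blue, green, red, nir), finite and
#'   nonnegative.
#' @param mode `"fixed"` or `"minmax"`.
#' @return H x W x 4 array with values in \[0, 1\].
#' @export
normalize_bands <- function(bands, mode = c("fixed", "minmax")) {
  mode <- match.arg(mode)
  if (!is.array(bands) || length(dim(bands)) != 3) stop("bands must be an H x W x B array", call. = FALSE)
  if (any(!is.finite(bands))) stop("bands contain non-finite values", call. = FALSE)
  if (any(bands < 0)) stop("bands contain negative values", call. = FALSE)
  if (mode == "fixed") {
    return(pmin(pmax(bands, 0), 1))
  }
  out <- bands
  for (b in seq_len(dim(bands)[3])) {
    v <- bands[, , b]
    rng <- range(v)
    out[, , b] <- if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else 0
  }
  out
}

#' Vegetation indices from the four mosaic bands
#'
#' Computes, pixelwise,
#' \deqn{ndvi = (nir - red) / (nir + red)}
#' \deqn{savi = (nir - red) / (nir + red + 0.5) \cdot 1.5}
#' \deqn{ndmi = (green - nir) / (green + nir)}
#' Zero denominators map to 0 so the stack stays finite for training. The
#' ndmi here is a green/nir moisture proxy usable with 4-band mosaics that
#' carry no SWIR band.
#'
#' @param bands H x W x 4 array in \[0, 1\], band order blue, green, red, nir.
#' @return H x W x 3 array (ndvi, savi, ndmi).
#' @export
compute_indices <- function(bands) {
  if (!is.array(bands) || length(dim(bands)) != 3 || dim(bands)[3] != 4) {
    stop("bands must be H x W x 4 (blue, green, red, nir)", call. = FALSE)
  }
  green <- bands[, , 2]
  red <- bands[, , 3]
  nir <- bands[, , 4]
  safe_ratio <- function(num, den) ifelse(den == 0, 0, num / den)
  ndvi <- safe_ratio(nir - red, nir + red)
  savi <- safe_ratio(nir - red, nir + red + 0.5) * 1.5
  ndmi <- safe_ratio(green - nir, green + nir)
  out <- array(0, dim = c(dim(bands)[1], dim(bands)[2], 3))
  out[, , 1] <- ndvi
  out[, , 2] <- savi
  out[, , 3] <- ndmi
  out
}

#' Channel names of the model-ready image stack
#' @export
stack_channels <- function() {
  c("blue", "green", "red", "nir", "ndvi", "savi", "ndmi")
}

#' Build the 7-channel model-ready stack
#'
#' Normalized bands plus the three indices, in the fixed channel order
#' `blue, green, red, nir, ndvi, savi, ndmi`.
#'
#' @inheritParams normalize_bands
#' @return H x W x 7 array with `dimnames[[3]]` set to the channel names.
#' @export
build_stack <- function(bands, mode = c("fixed", "minmax")) {
  nb <- normalize_bands(bands, mode)
  idx <- compute_indices(nb)
  out <- array(0, dim = c(dim(nb)[1], dim(nb)[2], 7),
               dimnames = list(NULL, NULL, stack_channels()))
  out[, , 1:4] <- nb
  out[, , 5:7] <- idx
  out
}

# 8- (or 4-) connected component labelling by min-label propagation.
# Returns an integer matrix: 0 outside the mask, component ids >= 1 inside.
label_components <- function(mask, connectivity = 8) {
  stopifnot(is.matrix(mask), connectivity %in% c(4, 8))
  h <- nrow(mask)
  w <- ncol(mask)
  lab <- matrix(Inf, h, w)
  lab[mask] <- which(mask)
  shift <- function(m, dr, dc) {
    out <- matrix(Inf, h, w)
    rs <- max(1, 1 + dr):min(h, h + dr)
    cs <- max(1, 1 + dc):min(w, w + dc)
    out[rs, cs] <- m[rs - dr, cs - dc]
    out
  }
  offs <- list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(-1, -1), c(-1, 1), c(1, -1), c(1, 1)))
  }
  repeat {
    new <- lab
    for (o in offs) new <- pmin(new, shift(lab, o[1], o[2]))
    new[!mask] <- Inf
    if (identical(new, lab)) break
    lab <- new
  }
  out <- matrix(0L, h, w)
  if (any(mask)) {
    ids <- lab[mask]
    out[mask] <- as.integer(match(ids, sort(unique(ids))))
  }
  out
}

#' Remove forest-loss patches below a minimum area
#'
#' Keeps only connected components of the loss mask whose area reaches
#' `min_area_ha` (default 3.8 ha, i.e. 1520 pixels at 5 m). Connectivity is
#' 8-connected by default (the more permissive filter) and configurable.
#'
#' @param loss_mask Logical matrix.
#' @param pixel_size Pixel edge length in metres.
#' @param min_area_ha Minimum component area in hectares.
#' @param connectivity 8 (default) or 4.
#' @return Logical matrix, a subset of the input mask.
#' @export
filter_min_patch <- function(loss_mask, pixel_size, min_area_ha = 3.8, connectivity = 8) {
  if (!is.matrix(loss_mask)) stop("loss_mask must be a matrix", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  mask <- loss_mask & !is.na(loss_mask)
  if (!any(mask)) return(mask)
  min_px <- ceiling(min_area_ha * 10000 / pixel_size^2)
  lab <- label_components(mask, connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= min_px)
  out <- matrix(FALSE, nrow(mask), ncol(mask))
  out[lab %in% keep_ids & lab > 0] <- TRUE
  out
}

#' Cut a stack (and optional labels) into model-ready patches
#'
#' Tiles the image with the given patch size and stride. If the dimensions do
#' not tile exactly, the image is padded at the bottom/right by edge
#' replication (labels padded with the ignore code) and
#' [reassemble_patches()] crops back to the original size. Patch positions
#' are recorded so argmax maps can be reassembled into a full-size map.
#'
#' @param stack H x W x C array.
#' @param labels Optional H x W integer matrix aligned with `stack`.
#' @param patch_size Patch edge length in pixels.
#' @param stride Step between patch origins; must be positive.
#' @param ignore_label Fill code for padded label pixels.
#' @return List with `patches` (each `list(x, labels, row0, col0)`), `dim`
#'   (original H, W) and `padded_dim`.
#' @export
extract_patches <- function(stack, labels = NULL, patch_size, stride = patch_size,
                            ignore_label = -1L) {
  d <- dim(stack)
  if (stride <= 0) stop("stride must be positive", call. = FALSE)
  if (patch_size > d[1] || patch_size > d[2]) stop("patch_size exceeds image size", call. = FALSE)
  starts <- function(n) {
    seq(1, by = stride, length.out = ceiling((n - patch_size) / stride) + 1)
  }
  rs <- starts(d[1])
  cs <- starts(d[2])
  ph <- max(rs) + patch_size - 1
  pw <- max(cs) + patch_size - 1
  pad_stack <- stack
  pad_labels <- labels
  if (ph > d[1] || pw > d[2]) {
    # edge replication for image channels, ignore code for labels
    pad_stack <- stack[pmin(seq_len(ph), d[1]), pmin(seq_len(pw), d[2]), , drop = FALSE]
    if (!is.null(labels)) {
      pad_labels <- matrix(ignore_label, ph, pw)
      pad_labels[seq_len(d[1]), seq_len(d[2])] <- labels
    }
  }
  patches <- list()
  for (r in rs) {
    for (cc in cs) {
      p <- list(
        x = pad_stack[r:(r + patch_size - 1), cc:(cc + patch_size - 1), , drop = FALSE],
        labels = if (!is.null(labels)) pad_labels[r:(r + patch_size - 1), cc:(cc + patch_size - 1)] else NULL,
        row0 = r, col0 = cc
      )
      patches[[length(patches) + 1]] <- p
    }
  }
  list(patches = patches, dim = d[1:2], padded_dim = c(ph, pw), patch_size = patch_size)
}

#' Reassemble per-patch class maps into a full-size map
#'
#' @param tiling The list returned by [extract_patches()].
#' @param maps List of patch-size class-map matrices, one per patch, in the
#'   same order as `tiling$patches`. Overlapping tiles are resolved by
#'   last-writer-wins, which is exact for non-overlapping tilings.
#' @return H x W integer matrix at the original image size.
#' @export
reassemble_patches <- function(tiling, maps) {
  stopifnot(length(maps) == length(tiling$patches))
  out <- matrix(NA_integer_, tiling$padded_dim[1], tiling$padded_dim[2])
  ps <- tiling$patch_size
  for (i in seq_along(maps)) {
    p <- tiling$patches[[i]]
    out[p$row0:(p$row0 + ps - 1), p$col0:(p$col0 + ps - 1)] <- maps[[i]]
  }
  out[seq_len(tiling$dim[1]), seq_len(tiling$dim[2]), drop = FALSE]
}
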