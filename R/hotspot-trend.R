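#' Pixel-centre coordinates of a class
#'
#' Converts the (strided) pixels of one class into lon/lat points at the
#' pixel centres via the scene's north-up affine geotransform.
#'
#' @param class_map H x W integer class map.
#' @param geotransform List with `origin_lon`, `origin_lat`, `px_deg` (the
#'   scene's upper-left corner and pixel size in degrees).
#' @param class_id Class code to extract.
#' @param stride Keep every `stride`-th row and column (subsampling for
#'   large rasters).
#' @return Tibble with columns `lon`, `lat` (possibly empty).
#' @export
class_points <- function(class_map, geotransform, class_id, stride = 1L) {
  stopifnot(is.matrix(class_map), stride >= 1)
  h <- nrow(class_map)
  w <- ncol(class_map)
  rows <- seq(1, h, by = stride)
  cols <- seq(1, w, by = stride)
  sub <- class_map[rows, cols, drop = FALSE]
  hit <- which(sub == class_id, arr.ind = TRUE)
  if (nrow(hit) == 0) return(tibble::tibble(lon = numeric(), lat = numeric()))
  r <- rows[hit[, 1]]
  cc <- cols[hit[, 2]]
  tibble::tibble(
    lon = geotransform$origin_lon + (cc - 0.5) * geotransform$px_deg,
    lat = geotransform$origin_lat - (r - 0.5) * geotransform$px_deg
  )
}

#' Kernel density hotspot grid
#'
#' Gaussian product-kernel density estimate evaluated at the centres of a
#' regular lon/lat grid (default 0.1 degree cells). The surface is scaled so
#' that its integral over the grid equals the number of input points (mass
#' conservation); the grid extent is padded by `pad_bandwidths` bandwidths so
#' essentially no kernel mass leaks off the grid.
#'
#' @param points Data frame with `lon`, `lat` columns (>= 1 point).
#' @param cell_size Grid cell edge in degrees (default 0.1).
#' @param bandwidth Gaussian kernel standard deviation in degrees (default
#'   0.1, matching the cell size).
#' @param extent Optional `c(lon_min, lon_max, lat_min, lat_max)`; default is
#'   the padded bounding box of the points.
#' @param pad_bandwidths Padding of the automatic extent, in bandwidths.
#' @param class_id Optional class code carried in the result.
#' @return A `lufor_density_grid`: list with `values` (nlat x nlon matrix,
#'   rows from north to south), `lon`, `lat` cell-centre vectors,
#'   `cell_size`, `bandwidth`, `n_points`, `class_id`.
#' @export
kde_hotspots <- function(points, cell_size = 0.1, bandwidth = 0.1,
                         extent = NULL, pad_bandwidths = 5, class_id = NA_integer_) {
  if (nrow(points) == 0) stop("empty point set", call. = FALSE)
  stopifnot(cell_size > 0, bandwidth > 0)
  if (is.null(extent)) {
    pad <- pad_bandwidths * bandwidth
    extent <- c(min(points$lon) - pad, max(points$lon) + pad,
                min(points$lat) - pad, max(points$lat) + pad)
  }
  lon_centres <- seq(extent[1] + cell_size / 2, extent[2], by = cell_size)
  lat_centres <- seq(extent[3] + cell_size / 2, extent[4], by = cell_size)
  # separable Gaussian kernel: density = (1/n) sum_p N(lon; p, h) N(lat; p, h),
  # computed as a product of two dense basis matrices
  Dlon <- outer(lon_centres, points$lon, function(g, p) dnorm(g - p, sd = bandwidth))
  Dlat <- outer(lat_centres, points$lat, function(g, p) dnorm(g - p, sd = bandwidth))
  dens <- Dlat %*% t(Dlon) # (nlat x nlon), point count units per square degree
  values <- dens[rev(seq_along(lat_centres)), , drop = FALSE] # north-up rows
  structure(list(
    values = values, lon = lon_centres, lat = rev(lat_centres),
    cell_size = cell_size, bandwidth = bandwidth,
    n_points = nrow(points), class_id = class_id,
    extent = extent
  ), class = "lufor_density_grid")
}

#' Integrated mass of a density grid
#'
#' `sum(values) * cell_area`; equals the number of input points up to
#' quadrature and edge truncation error.
#'
#' @param grid A `lufor_density_grid`.
#' @export
grid_mass <- function(grid) {
  sum(grid$values) * grid$cell_size^2
}

#' @export
print.lufor_density_grid <- function(x, ...) {
  cat(sprintf("<lufor_density_grid> %d x %d cells of %.3g deg, %d points, mass %.2f\n",
              nrow(x$values), ncol(x$values), x$cell_size, x$n_points, grid_mass(x)))
  invisible(x)
}

#' @export
tidy.lufor_density_grid <- function(x, ...) {
  tibble::tibble(
    lon = rep(x$lon, each = length(x$lat)),
    lat = rep(x$lat, length(x$lon)),
    density = as.vector(x$values),
    class_id = x$class_id
  )
}

#' Plot a density grid as a heat map
#' @param object A `lufor_density_grid`.
#' @param ... Unused.
#' @export
autoplot.lufor_density_grid <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data$density)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude", fill = "density") +
    ggplot2::theme_minimal()
}

#' Area and proportion of each class per region and lustrum
#'
#' Counts pixels per (region, class, lustrum), converts to areas with the
#' pixel size, and normalizes proportions within each (region, lustrum) so
#' they sum to 1. Only loss pixels (lustrum defined) enter the table.
#' Log scaling, when wanted for display, is applied at plot time only.
#'
#' @param class_map H x W class map (codes `0..K-1`; others excluded).
#' @param loss_year H x W loss-year matrix (0 = no loss).
#' @param region_map H x W region identifiers (character or integer matrix),
#'   or a single id for a whole-scene region.
#' @param pixel_size Pixel edge length in metres.
#' @param n_classes K.
#' @return Tibble `region_id`, `class_id`, `lustrum`, `area_ha`,
#'   `proportion`.
#' @export
lustrum_region_trend <- function(class_map, loss_year, region_map, pixel_size,
                                 n_classes = max(class_map) + 1L) {
  if (length(region_map) == 1) {
    region_map <- matrix(region_map, nrow(class_map), ncol(class_map))
  }
  if (!all(dim(class_map) == dim(loss_year)) || !all(dim(class_map) == dim(region_map))) {
    stop("rasters are not aligned", call. = FALSE)
  }
  lus <- lustrum_of(loss_year)
  keep <- !is.na(lus) & class_map >= 0 & class_map < n_classes
  if (!any(keep)) {
    return(tibble::tibble(region_id = character(), class_id = integer(),
                          lustrum = character(), area_ha = numeric(),
                          proportion = numeric()))
  }
  px_ha <- pixel_size^2 / 10000
  df <- tibble::tibble(
    region_id = as.character(region_map[keep]),
    class_id = as.integer(class_map[keep]),
    lustrum = lustrum_labels()[lus[keep]]
  )
  df |>
    dplyr::count(.data$region_id, .data$class_id, .data$lustrum, name = "n_px") |>
    dplyr::mutate(area_ha = .data$n_px * px_ha) |>
    dplyr::group_by(.data$region_id, .data$lustrum) |>
    dplyr::mutate(proportion = .data$area_ha / sum(.data$area_ha)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n_px")
}

#' Plot trend tables per region and lustrum
#'
#' @param trend A [lustrum_region_trend()] tibble.
#' @param measure `"area"` (log10 y scale) or `"proportion"`.
#' @export
plot_trend <- function(trend, measure = c("area", "proportion")) {
  measure <- match.arg(measure)
  y <- if (measure == "area") "area_ha" else "proportion"
  p <- ggplot2::ggplot(trend, ggplot2::aes(x = .data$lustrum,
                                           y = .data[[y]],
                                           colour = factor(.data$class_id),
                                           group = .data$class_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~region_id) +
    ggplot2::labs(x = NULL, colour = "class",
                  y = if (measure == "area") "area (ha, log10)" else "proportion") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (measure == "area") p <- p + ggplot2::scale_y_log10()
  p
}

#' Per-country class percentages
#'
#' For each country, the percentage of its classified pixels in each class;
#' percentages sum to 100 per country.
#'
#' @param class_map H x W class map (codes `0..K-1`; others excluded).
#' @param country_map H x W country identifiers, or a single id.
#' @param n_classes K.
#' @return Tibble `country_id`, `class_id`, `percent`.
#' @export
country_proportions <- function(class_map, country_map,
                                n_classes = max(class_map) + 1L) {
  if (length(country_map) == 1) {
    country_map <- matrix(country_map, nrow(class_map), ncol(class_map))
  }
  if (!all(dim(class_map) == dim(country_map))) stop("rasters are not aligned", call. = FALSE)
  keep <- class_map >= 0 & class_map < n_classes
  if (!any(keep)) stop("no classified pixels", call. = FALSE)
  tibble::tibble(
    country_id = as.character(country_map[keep]),
    class_id = as.integer(class_map[keep])
  ) |>
    dplyr::count(.data$country_id, .data$class_id) |>
    dplyr::group_by(.data$country_id) |>
    dplyr::mutate(percent = 100 * .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::select(-"n")
}
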