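#' Configuration for a synthetic scene
#'
#' Describes one synthetic mosaic tile: its size, pixel resolution, the class
#' catalogue with spectral signatures and shape families, object density,
#' scene-level sensor noise, the fraction of non-water pixels carrying forest
#' loss, and the geographic anchor used to build the north-up affine
#' geotransform.
#'
#' @param height,width Scene size in pixels (>= 32).
#' @param pixel_size Pixel edge length in metres (default 5, emulating
#'   ~4.77 m mosaics).
#' @param classes Class catalogue tibble, see [default_classes()].
#' @param n_objects_per_class Integer range (length 2) of objects painted per
#'   class.
#' @param noise_sd Scene-level additive Gaussian noise (reflectance units) on
#'   top of the per-class `band_sd`.
#' @param loss_fraction Target fraction of non-water pixels covered by the
#'   forest-loss mask.
#' @param region_id,country_id Categorical identifiers carried through to
#'   trend and country summaries.
#' @param origin_lon,origin_lat Upper-left corner of the scene in degrees.
#' @param seed Integer seed; every generator output is a pure function of the
#'   configuration including this seed.
#' @return A list of class `lufor_scene_config`.
#' @export
scene_config <- function(height = 128, width = 128, pixel_size = 5,
                         classes = default_classes(),
                         n_objects_per_class = c(1L, 3L),
                         noise_sd = 0.01, loss_fraction = 0.35,
                         region_id = "western", country_id = "A",
                         origin_lon = 10, origin_lat = 5, seed = 1L) {
  if (height < 32 || width < 32) stop("height and width must be >= 32", call. = FALSE)
  if (pixel_size <= 0) stop("pixel_size must be positive", call. = FALSE)
  if (nrow(classes) < 1) stop("need at least one class", call. = FALSE)
  validate_classes(classes)
  cfg <- list(
    height = as.integer(height), width = as.integer(width),
    pixel_size = pixel_size, classes = classes,
    n_objects_per_class = as.integer(n_objects_per_class),
    noise_sd = noise_sd, loss_fraction = loss_fraction,
    region_id = region_id, country_id = country_id,
    origin_lon = origin_lon, origin_lat = origin_lat,
    seed = as.integer(seed)
  )
  class(cfg) <- "lufor_scene_config"
  cfg
}

# ---- shape painters ---------------------------------------------------------
# each painter mutates a truth matrix in place (by returning it)

paint_rect <- function(truth, id, h0, w0, hh, ww) {
  h <- nrow(truth); w <- ncol(truth)
  r1 <- max(1, h0); r2 <- min(h, h0 + hh - 1)
  c1 <- max(1, w0); c2 <- min(w, w0 + ww - 1)
  if (r1 > r2 || c1 > c2) return(truth) # object entirely off-canvas
  truth[r1:r2, c1:c2] <- id
  truth
}

paint_blob <- function(truth, id, cy, cx, ry, rx) {
  h <- nrow(truth); w <- ncol(truth)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  inside <- ((rows - cy) / ry)^2 + ((cols - cx) / rx)^2 <= 1
  truth[inside] <- id
  truth
}

paint_polyline <- function(truth, id, thickness) {
  h <- nrow(truth); w <- ncol(truth)
  # straight-ish line crossing the full scene with a random slope
  vertical <- runif(1) < 0.5
  intercept <- runif(1, 0.2, 0.8)
  slope <- runif(1, -0.4, 0.4)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  if (vertical) {
    centre <- intercept * w + slope * (rows - h / 2)
    hit <- abs(cols - centre) <= thickness / 2
  } else {
    centre <- intercept * h + slope * (cols - w / 2)
    hit <- abs(rows - centre) <= thickness / 2
  }
  truth[hit] <- id
  truth
}

paint_meander <- function(truth, id, thickness) {
  h <- nrow(truth); w <- ncol(truth)
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  amp <- runif(1, 0.05, 0.15) * h
  per <- runif(1, 0.5, 1.5) * w
  phase <- runif(1, 0, 2 * pi)
  centre <- runif(1, 0.25, 0.75) * h + amp * sin(2 * pi * cols / per + phase)
  truth[abs(rows - centre) <= thickness / 2] <- id
  truth
}

paint_cluster <- function(truth, id, cy, cx) {
  n <- sample(4:8, 1)
  for (i in seq_len(n)) {
    hh <- sample(3:6, 1); ww <- sample(3:6, 1)
    truth <- paint_rect(truth, id,
                        round(cy + rnorm(1, 0, nrow(truth) / 16)),
                        round(cx + rnorm(1, 0, ncol(truth) / 16)), hh, ww)
  }
  truth
}

paint_class_objects <- function(truth, spec, n_objects) {
  h <- nrow(truth); w <- ncol(truth)
  id <- spec$class_id
  for (i in seq_len(n_objects)) {
    switch(spec$geometry_kind,
      field = ,
      lattice_plantation = {
        hh <- sample(round(h / 8):round(h / 3), 1)
        ww <- sample(round(w / 8):round(w / 3), 1)
        truth <- paint_rect(truth, id, sample(h, 1), sample(w, 1), hh, ww)
      },
      blob = {
        truth <- paint_blob(truth, id, runif(1, 1, h), runif(1, 1, w),
                            runif(1, h / 12, h / 5), runif(1, w / 12, w / 5))
      },
      polyline = truth <- paint_polyline(truth, id, thickness = sample(2:3, 1)),
      meander = truth <- paint_meander(truth, id, thickness = sample(3:5, 1)),
      cluster = truth <- paint_cluster(truth, id, runif(1, 1, h), runif(1, 1, w)),
      texture = {
        # texture classes form the matrix/background; extra objects are
        # painted as large soft blobs
        truth <- paint_blob(truth, id, runif(1, 1, h), runif(1, 1, w),
                            runif(1, h / 6, h / 3), runif(1, w / 6, w / 3))
      }
    )
  }
  truth
}

# smooth random field in [0,1] used for the loss mask, built from a coarse
# Gaussian grid upsampled bilinearly
smooth_field <- function(h, w, coarse = 8) {
  g <- matrix(rnorm((coarse + 1)^2), coarse + 1, coarse + 1)
  ry <- seq(1, coarse + 1, length.out = h)
  cx <- seq(1, coarse + 1, length.out = w)
  r0 <- pmin(floor(ry), coarse); c0 <- pmin(floor(cx), coarse)
  fr <- ry - r0; fc <- cx - c0
  a <- g[cbind(rep(r0, w), rep(c0, each = h))]
  b <- g[cbind(rep(r0 + 1, w), rep(c0, each = h))]
  cc <- g[cbind(rep(r0, w), rep(c0 + 1, each = h))]
  d <- g[cbind(rep(r0 + 1, w), rep(c0 + 1, each = h))]
  fr <- rep(fr, w); fc <- rep(fc, each = h)
  v <- a * (1 - fr) * (1 - fc) + b * fr * (1 - fc) + cc * (1 - fr) * fc + d * fr * fc
  matrix(v, h, w)
}

#' Generate a synthetic scene
#'
#' Paints the configured land-use classes with their shape families
#' (fields, plantation lattices, roads, meandering rivers, blobs, settlement
#' clusters) onto a background matrix, synthesizes the four reflectance bands
#' as the class spectral signature plus Gaussian noise, draws a spatially
#' coherent forest-loss mask over non-water pixels with a per-pixel loss year
#' uniform on 2001--2020, and attaches a north-up lon/lat geotransform.
#' Plantation-lattice classes receive a small zero-mean periodic brightness
#' modulation emulating crown/soil alternation.
#'
#' Deterministic: the same configuration (including its seed) always yields a
#' bit-identical scene. Every configured class is guaranteed at least one
#' pixel.
#'
#' @param config A [scene_config()].
#' @return A `lufor_scene`: list with `bands` (H x W x 4 in \[0, 1\]),
#'   `truth_mask`, `loss_mask`, `loss_year`, `geotransform`, `pixel_size`,
#'   `region_id`, `country_id`, `classes`, `config`.
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "lufor_scene_config"))
  withr::with_seed(config$seed, generate_scene_impl(config))
}

generate_scene_impl <- function(config) {
  h <- config$height; w <- config$width
  classes <- config$classes
  k <- nrow(classes)
  # background: the first texture-kind class, else the most common fallback
  bg_row <- which(classes$geometry_kind == "texture")
  bg <- if (length(bg_row) > 0) classes$class_id[bg_row[1]] else classes$class_id[1]
  truth <- matrix(as.integer(bg), h, w)

  # paint in priority order so linear features stay on top
  prio <- c(texture = 1, blob = 2, field = 3, lattice_plantation = 4,
            cluster = 5, polyline = 6, meander = 7)
  ord <- order(prio[classes$geometry_kind], classes$class_id)
  nobj <- config$n_objects_per_class
  for (i in ord) {
    spec <- as.list(classes[i, ])
    n <- if (nobj[1] >= nobj[2]) nobj[1] else sample(nobj[1]:nobj[2], 1)
    if (spec$class_id == bg) n <- max(0L, n - 1L) # background already covers
    if (n > 0) truth <- paint_class_objects(truth, spec, n)
  }
  # guarantee presence of every class
  for (i in sample(seq_len(k))) {
    id <- classes$class_id[i]
    if (!any(truth == id)) {
      truth <- paint_rect(truth, id, sample(h - 5, 1), sample(w - 5, 1), 5, 5)
    }
  }

  # bands: class signature + lattice modulation + noise, clipped to [0,1]
  means <- class_band_means(classes)
  sds <- classes$band_sd
  row_of_id <- match(as.vector(truth), classes$class_id)
  bands <- array(0, dim = c(h, w, 4))
  lattice_ids <- classes$class_id[classes$geometry_kind == "lattice_plantation"]
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  modulation <- 0.02 * sin(2 * pi * rows / 4) * sin(2 * pi * cols / 4)
  mod_mask <- matrix(truth %in% lattice_ids, h, w)
  for (b in 1:4) {
    mu <- means[row_of_id, b]
    noise <- rnorm(h * w, 0, sds[row_of_id]) + rnorm(h * w, 0, config$noise_sd)
    v <- matrix(mu + noise, h, w)
    v[mod_mask] <- v[mod_mask] + modulation[mod_mask]
    bands[, , b] <- pmin(pmax(v, 0), 1)
  }

  # forest loss: threshold a smooth field over non-water pixels
  water_ids <- classes$class_id[classes$name == "water"]
  eligible <- !(truth %in% water_ids)
  eligible <- matrix(eligible, h, w)
  loss_mask <- matrix(FALSE, h, w)
  if (config$loss_fraction > 0 && any(eligible)) {
    field <- smooth_field(h, w)
    thr <- stats::quantile(field[eligible], probs = 1 - config$loss_fraction)
    loss_mask <- eligible & field >= thr
  }
  loss_year <- matrix(0L, h, w)
  loss_year[loss_mask] <- sample(2001:2020, sum(loss_mask), replace = TRUE)

  scene <- list(
    bands = bands, truth_mask = truth, loss_mask = loss_mask,
    loss_year = loss_year,
    geotransform = list(
      origin_lon = config$origin_lon, origin_lat = config$origin_lat,
      px_deg = config$pixel_size / 111320
    ),
    pixel_size = config$pixel_size,
    region_id = config$region_id, country_id = config$country_id,
    classes = classes, config = config
  )
  class(scene) <- "lufor_scene"
  scene
}

#' @export
print.lufor_scene <- function(x, ...) {
  cat(sprintf("<lufor_scene> %d x %d px at %.2f m, %d classes, %.1f%% loss\n",
              nrow(x$truth_mask), ncol(x$truth_mask), x$pixel_size,
              nrow(x$classes), 100 * mean(x$loss_mask)))
  invisible(x)
}

#' Corruption settings for reference annotations
#'
#' Emulates the pathologies of real reference polygons: dislocated
#' boundaries, polygons containing a mix of land uses, wrong labels, and
#' missing labels (the unlabeled code -1).
#'
#' @param boundary_shift_px Maximum boundary dislocation in pixels (>= 0).
#' @param mislabel_fraction Fraction of labeled pixels given a wrong class.
#' @param drop_fraction Fraction of pixels set to unlabeled (-1).
#' @param polygon_mix_fraction Fraction of annotation polygons (connected
#'   components) receiving an inclusion of a different class.
#' @param seed Integer seed.
#' @return A list of class `lufor_corruption_config`.
#' @export
corruption_config <- function(boundary_shift_px = 0L, mislabel_fraction = 0,
                              drop_fraction = 0, polygon_mix_fraction = 0,
                              seed = 1L) {
  fr <- c(mislabel_fraction, drop_fraction, polygon_mix_fraction)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]", call. = FALSE)
  if (boundary_shift_px < 0) stop("boundary_shift_px must be >= 0", call. = FALSE)
  structure(list(
    boundary_shift_px = as.integer(boundary_shift_px),
    mislabel_fraction = mislabel_fraction, drop_fraction = drop_fraction,
    polygon_mix_fraction = polygon_mix_fraction, seed = as.integer(seed)
  ), class = "lufor_corruption_config")
}

#' Corrupt a clean annotation mask
#'
#' Applies, in order: boundary dislocation (the whole label field is shifted
#' by a random offset of up to `boundary_shift_px` pixels with edge
#' replication), polygon mixing (a random sub-block inside a fraction of the
#' connected annotation components is overwritten with a different class),
#' mislabeling (an exact `round(f * n)` count of labeled pixels receives a
#' guaranteed-different class, so the measured mislabel rate matches the
#' requested fraction), and label dropping (pixels set to -1). Deterministic
#' per seed.
#'
#' @param truth_mask Integer class matrix with codes in `0..K-1`.
#' @param corruption A [corruption_config()].
#' @param n_classes Number of classes K (default: max code + 1).
#' @return Integer matrix of the same shape; -1 marks unlabeled pixels.
#' @export
corrupt_annotations <- function(truth_mask, corruption,
                                n_classes = max(truth_mask) + 1L) {
  stopifnot(inherits(corruption, "lufor_corruption_config"), is.matrix(truth_mask))
  withr::with_seed(corruption$seed, {
    h <- nrow(truth_mask); w <- ncol(truth_mask)
    lab <- truth_mask

    if (corruption$boundary_shift_px > 0) {
      s <- corruption$boundary_shift_px
      dr <- sample(-s:s, 1); dc <- sample(-s:s, 1)
      ridx <- pmin(pmax(seq_len(h) - dr, 1), h)
      cidx <- pmin(pmax(seq_len(w) - dc, 1), w)
      lab <- lab[ridx, cidx]
    }

    if (corruption$polygon_mix_fraction > 0) {
      comp <- label_components_by_class(lab)
      ids <- seq_len(max(comp))
      pick <- ids[runif(length(ids)) < corruption$polygon_mix_fraction]
      for (id in pick) {
        px <- which(comp == id, arr.ind = TRUE)
        if (nrow(px) < 9) next
        ctr <- px[sample(nrow(px), 1), ]
        hh <- max(2, round(sqrt(nrow(px)) / 2))
        other <- (lab[ctr[1], ctr[2]] + sample(n_classes - 1, 1)) %% n_classes
        lab <- paint_rect(lab, as.integer(other), ctr[1] - hh %/% 2, ctr[2] - hh %/% 2, hh, hh)
      }
    }

    if (corruption$mislabel_fraction > 0) {
      labeled <- which(lab >= 0)
      m <- round(corruption$mislabel_fraction * length(labeled))
      if (m > 0) {
        tgt <- sample(labeled, m)
        lab[tgt] <- (lab[tgt] + sample(n_classes - 1, m, replace = TRUE)) %% n_classes
      }
    }

    if (corruption$drop_fraction > 0) {
      m <- round(corruption$drop_fraction * length(lab))
      if (m > 0) lab[sample(length(lab), m)] <- -1L
    }
    storage.mode(lab) <- "integer"
    lab
  })
}

# connected components of equal-valued regions of a label map
label_components_by_class <- function(lab) {
  out <- matrix(0L, nrow(lab), ncol(lab))
  nxt <- 0L
  for (v in sort(unique(as.vector(lab)))) {
    cc <- label_components(lab == v, connectivity = 8)
    out[cc > 0] <- cc[cc > 0] + nxt
    nxt <- nxt + max(cc)
  }
  out
}

#' Partition scene indices into the three pools
#'
#' The pure bookkeeping behind [generate_dataset()]: a seeded shuffle of
#' `n` items assigns `floor(annotated_fraction * n)` to the annotated pool,
#' `max(1, floor(test_fraction * n))` to the independent test pool, and the
#' rest to the unannotated pool. The three pools are disjoint by
#' construction.
#'
#' @param n Number of items.
#' @param annotated_fraction,test_fraction Pool fractions (annotated + test
#'   must fit inside n).
#' @param seed Shuffle seed.
#' @return Character vector of length `n` with values `"annotated"`,
#'   `"unannotated"`, `"test"`.
#' @export
partition_pools <- function(n, annotated_fraction, test_fraction = 0.2, seed = 1L) {
  n_ann <- floor(annotated_fraction * n)
  n_test <- max(1L, floor(test_fraction * n))
  if (n_ann + n_test > n) stop("pools exceed the number of items", call. = FALSE)
  withr::with_seed(seed, {
    ord <- sample(n)
    p <- rep("unannotated", n)
    p[ord[seq_len(n_ann)]] <- "annotated"
    p[ord[n_ann + seq_len(n_test)]] <- "test"
    p
  })
}

#' Generate a full dataset with three pools
#'
#' Generates `n_scenes` seeded scenes (seeds derived from `seed`), scattering
#' them over four regions with two countries each, then partitions them into
#' the three pools of pool-based active learning: an annotated training pool
#' carrying corrupted reference labels, an unannotated pool whose clean truth
#' stays hidden until the simulated annotator reveals it, and an independent
#' test pool with clean labels that never changes.
#'
#' @param n_scenes Number of scenes (>= 3).
#' @param config A [scene_config()] template; per-scene seed, region, country
#'   and origin are varied by the generator.
#' @param corruption A [corruption_config()] applied to annotated-pool labels.
#' @param annotated_fraction Fraction of scenes initially annotated;
#'   `floor(annotated_fraction * n_scenes)` scenes.
#' @param test_fraction Fraction held out as the independent test pool
#'   (default 0.2, at least 1 scene).
#' @param seed Master seed for scene generation and pool assignment.
#' @return A `lufor_pools` object: named scene list, named label list for the
#'   annotated pool, and a manifest tibble (`scene_id`, `pool`, `region_id`,
#'   `country_id`, `cycle_of_annotation`).
#' @export
generate_dataset <- function(n_scenes, config = scene_config(),
                             corruption = corruption_config(),
                             annotated_fraction = 0.4, test_fraction = 0.2,
                             seed = 1L) {
  if (n_scenes < 3) stop("need at least 3 scenes to populate three pools", call. = FALSE)
  n_ann <- floor(annotated_fraction * n_scenes)
  n_test <- max(1L, floor(test_fraction * n_scenes))
  if (n_ann + n_test > n_scenes) stop("annotated_fraction + test_fraction exceed the dataset", call. = FALSE)

  regions <- c("western", "central", "eastern", "southern")
  region_centres <- list(
    western = c(lon = 0, lat = 8), central = c(lon = 20, lat = 0),
    eastern = c(lon = 35, lat = -2), southern = c(lon = 25, lat = -18)
  )
  scenes <- vector("list", n_scenes)
  ids <- sprintf("scene_%03d", seq_len(n_scenes))
  meta <- withr::with_seed(derive_seed(seed, "scenes"), {
    lapply(seq_len(n_scenes), function(i) {
      region <- regions[((i - 1) %% 4) + 1]
      ctr <- region_centres[[region]]
      list(region = region,
           country = paste0(region, "_", c("A", "B")[((i - 1) %/% 4) %% 2 + 1]),
           lon = ctr["lon"] + runif(1, -2, 2), lat = ctr["lat"] + runif(1, -2, 2))
    })
  })
  for (i in seq_len(n_scenes)) {
    cfg_i <- config
    cfg_i$seed <- derive_seed(seed, "scenes") + i
    cfg_i$region_id <- meta[[i]]$region
    cfg_i$country_id <- meta[[i]]$country
    cfg_i$origin_lon <- unname(meta[[i]]$lon)
    cfg_i$origin_lat <- unname(meta[[i]]$lat)
    scenes[[i]] <- generate_scene(cfg_i)
  }
  names(scenes) <- ids

  pool <- partition_pools(n_scenes, annotated_fraction, test_fraction,
                          seed = derive_seed(seed, "pools"))

  labels <- list()
  for (i in which(pool == "annotated")) {
    cor_i <- corruption
    cor_i$seed <- derive_seed(seed, "corrupt") + i
    labels[[ids[i]]] <- corrupt_annotations(scenes[[i]]$truth_mask, cor_i,
                                            n_classes = nrow(config$classes))
  }

  manifest <- tibble::tibble(
    scene_id = ids,
    pool = pool,
    region_id = purrr::map_chr(scenes, "region_id"),
    country_id = purrr::map_chr(scenes, "country_id"),
    cycle_of_annotation = ifelse(pool == "annotated", 0L, NA_integer_)
  )
  structure(list(
    scenes = scenes, labels = labels, manifest = manifest,
    n_classes = nrow(config$classes), classes = config$classes
  ), class = "lufor_pools")
}

#' @export
print.lufor_pools <- function(x, ...) {
  tab <- table(x$manifest$pool)
  cat("<lufor_pools>", paste(names(tab), tab, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Scene ids of a pool
#' @param pools A `lufor_pools` object.
#' @param which Pool name: "annotated", "unannotated" or "test".
#' @export
pool_ids <- function(pools, which) {
  stopifnot(inherits(pools, "lufor_pools"))
  pools$manifest$scene_id[pools$manifest$pool == which]
}
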