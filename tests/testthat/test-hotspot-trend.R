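gt <- list(origin_lon = 20, origin_lat = 0, px_deg = 0.01)

test_that("class pixels map to centre coordinates through the affine transform", {
  cm <- matrix(0L, 10, 10)
  cm[3, 7] <- 1L
  pts <- class_points(cm, gt, class_id = 1)
  expect_equal(nrow(pts), 1)
  expect_equal(pts$lon, 20 + 6.5 * 0.01)
  expect_equal(pts$lat, 0 - 2.5 * 0.01)

  expect_equal(nrow(class_points(cm, gt, class_id = 9)), 0)

  full <- matrix(1L, 20, 20)
  expect_equal(nrow(class_points(full, gt, 1, stride = 2)), 100) # ~1/4 of 400
})

test_that("the density grid conserves mass and is linear in the points", {
  withr::with_seed(31, {
    pts <- tibble::tibble(lon = runif(400, 10, 11), lat = runif(400, -1, 0))
  })
  grid <- kde_hotspots(pts, cell_size = 0.1, bandwidth = 0.1)
  expect_true(all(grid$values >= 0))
  expect_equal(grid_mass(grid), 400, tolerance = 0.01)

  doubled <- kde_hotspots(dplyr::bind_rows(pts, pts), cell_size = 0.1,
                          bandwidth = 0.1, extent = grid$extent)
  expect_equal(doubled$values, 2 * grid$values, tolerance = 1e-9)

  # order invariance
  shuffled <- kde_hotspots(pts[sample(nrow(pts)), ], cell_size = 0.1,
                           bandwidth = 0.1, extent = grid$extent)
  expect_equal(shuffled$values, grid$values)

  expect_error(kde_hotspots(tibble::tibble(lon = numeric(), lat = numeric())),
               "empty")
})

test_that("a single point yields a unimodal surface peaking at its cell", {
  g <- kde_hotspots(tibble::tibble(lon = 5, lat = 5), cell_size = 0.1, bandwidth = 0.1)
  peak <- which(g$values == max(g$values), arr.ind = TRUE)
  expect_lt(abs(g$lon[peak[2]] - 5), 0.1)
  expect_lt(abs(g$lat[peak[1]] - 5), 0.1)
  expect_equal(grid_mass(g), 1, tolerance = 0.01)
})

test_that("clustered points concentrate density more than uniform points", {
  withr::with_seed(32, {
    unif <- tibble::tibble(lon = runif(2000, 0, 2), lat = runif(2000, 0, 2))
    clus <- tibble::tibble(lon = rnorm(2000, 1, 0.05), lat = rnorm(2000, 1, 0.05))
  })
  ext <- c(-0.5, 2.5, -0.5, 2.5)
  gu <- kde_hotspots(unif, 0.1, 0.1, extent = ext)
  gc <- kde_hotspots(clus, 0.1, 0.1, extent = ext)
  cv <- function(v) stats::sd(v) / mean(v)
  expect_lt(cv(gu$values), cv(gc$values))
})

test_that("the density surface agrees with an independent bivariate KDE", {
  skip_if_not_installed("MASS")
  withr::with_seed(33, {
    pts <- tibble::tibble(lon = rnorm(300, 0, 0.3), lat = rnorm(300, 0, 0.3))
  })
  ext <- c(-1.5, 1.5, -1.5, 1.5)
  g <- kde_hotspots(pts, cell_size = 0.1, bandwidth = 0.1, extent = ext)
  # MASS::kde2d uses sd = h/4 and returns a density integrating to 1
  kk <- MASS::kde2d(pts$lon, pts$lat, h = 0.4, n = length(g$lon),
                    lims = c(ext[1] + 0.05, ext[2] - 0.05, ext[3] + 0.05, ext[4] - 0.05))
  ours <- g$values[rev(seq_along(g$lat)), ] # back to south-up rows
  ref <- t(kk$z) * nrow(pts)               # kde2d is (x, y); ours is (lat, lon)
  expect_equal(max(abs(ours - ref)) / max(ref), 0, tolerance = 1e-6)
})

test_that("trend tables normalize proportions within region and lustrum", {
  withr::with_seed(34, {
    cm <- matrix(sample(0:4, 1600, TRUE), 40, 40)
    yr <- matrix(sample(c(0L, 2001:2020), 1600, TRUE), 40, 40)
    reg <- matrix(rep(c("west", "east"), each = 800), 40, 40)
  })
  tt <- lustrum_region_trend(cm, yr, reg, pixel_size = 5, n_classes = 5)
  sums <- tt |>
    dplyr::group_by(region_id, lustrum) |>
    dplyr::summarise(s = sum(proportion), .groups = "drop")
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
  expect_true(all(tt$area_ha >= 0))

  # doubling the pixel size quadruples areas, proportions unchanged
  tt2 <- lustrum_region_trend(cm, yr, reg, pixel_size = 10, n_classes = 5)
  j <- dplyr::inner_join(tt, tt2, by = c("region_id", "class_id", "lustrum"))
  expect_equal(j$area_ha.y, 4 * j$area_ha.x)
  expect_equal(j$proportion.y, j$proportion.x)

  # hand-counted toy: one region, one class per lustrum
  cm1 <- matrix(0L, 2, 4)
  yr1 <- matrix(c(2001L, 2001L, 2006L, 2006L, 2011L, 2011L, 2016L, 2016L), 2, 4)
  t1 <- lustrum_region_trend(cm1, yr1, "r", pixel_size = 100, n_classes = 1)
  expect_equal(nrow(t1), 4)
  expect_equal(t1$area_ha, rep(2, 4)) # 2 px * 1 ha
  expect_equal(t1$proportion, rep(1, 4))
})

test_that("country percentages sum to one hundred", {
  cm <- matrix(c(0L, 0L, 1L, 1L), 2, 2)
  half <- country_proportions(cm, "X", n_classes = 2)
  expect_equal(half$percent, c(50, 50))

  whole <- country_proportions(matrix(3L, 4, 4), "Y", n_classes = 4)
  expect_equal(whole$percent, 100)

  withr::with_seed(35, {
    cm3 <- matrix(sample(0:2, 900, TRUE), 30, 30)
    ctry <- matrix(sample(c("A", "B", "C"), 900, TRUE), 30, 30)
  })
  cp <- country_proportions(cm3, ctry, n_classes = 3)
  tot <- cp |> dplyr::group_by(country_id) |> dplyr::summarise(s = sum(percent))
  expect_equal(tot$s, rep(100, 3), tolerance = 1e-6)
  # spot-check one hand-computed cell
  expect_equal(cp$percent[cp$country_id == "A" & cp$class_id == 0],
               100 * sum(cm3 == 0 & ctry == "A") / sum(ctry == "A"))

  # no-data pixels are excluded from the denominators
  cmnd <- cm3
  cmnd[ctry == "B"] <- 255L
  expect_error(country_proportions(matrix(255L, 2, 2), "Z", n_classes = 3), "no classified")
})
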