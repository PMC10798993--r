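test_that("class catalogue is well-formed and spectrally separable", {
  cls <- default_classes()
  expect_equal(nrow(cls), 15)
  expect_false(anyDuplicated(cls$class_id) > 0)
  bm <- class_band_means(cls)
  expect_true(all(bm >= 0 & bm <= 1))
  # pairwise spectral distances large relative to the default noise level
  d <- as.matrix(dist(bm))
  diag(d) <- Inf
  expect_gt(min(d), 3 * max(cls$band_sd))
})

test_that("scene generation is deterministic and respects its configuration", {
  cfg <- scene_config(height = 64, width = 64, seed = 11)
  s1 <- generate_scene(cfg)
  s2 <- generate_scene(cfg)
  expect_identical(s1$bands, s2$bands)
  expect_identical(s1$truth_mask, s2$truth_mask)
  expect_identical(s1$loss_year, s2$loss_year)

  expect_true(all(s1$bands >= 0 & s1$bands <= 1))
  expect_true(all(is.finite(s1$bands)))
  k <- nrow(cfg$classes)
  expect_true(all(s1$truth_mask %in% 0:(k - 1)))
  # every configured class occupies at least one pixel
  expect_setequal(sort(unique(as.vector(s1$truth_mask))), 0:(k - 1))
  # loss year defined exactly on the loss mask
  expect_true(all((s1$loss_year > 0) == s1$loss_mask))
  expect_true(all(s1$loss_year[s1$loss_mask] %in% 2001:2020))
  # water carries no forest loss
  water <- cfg$classes$class_id[cfg$classes$name == "water"]
  expect_false(any(s1$loss_mask[s1$truth_mask == water]))
})

test_that("a single-class configuration yields a constant scene at its signature", {
  cls <- default_classes()
  water <- cls[cls$name == "water", ]
  cfg <- scene_config(height = 32, width = 32, classes = water, seed = 1)
  sc <- generate_scene(cfg)
  expect_true(all(sc$truth_mask == water$class_id))
  # bands sit at the water signature within a few noise standard deviations
  for (b in 1:4) {
    mu <- class_band_means(water)[1, b]
    expect_lt(abs(mean(sc$bands[, , b]) - mu), 4 * (water$band_sd + 0.01) / sqrt(32 * 32) + 0.005)
  }
  expect_error(scene_config(classes = cls[0, ]), "class")
  expect_error(scene_config(height = 8, width = 8), "32")
})

test_that("per-class band means match the configured spectra", {
  cfg <- scene_config(height = 256, width = 256, seed = 7, noise_sd = 0)
  sc <- generate_scene(cfg)
  means <- class_band_means(cfg$classes)
  for (i in seq_len(nrow(cfg$classes))) {
    id <- cfg$classes$class_id[i]
    px <- sc$truth_mask == id
    n <- sum(px)
    if (n < 30) next
    # clipping to [0,1] and lattice modulation add slight bias; 3 SE plus a
    # small absolute allowance covers the truncation of near-zero signatures
    tol <- 3 * cfg$classes$band_sd[i] / sqrt(n) + 0.012
    for (b in 1:4) {
      expect_lt(abs(mean(sc$bands[, , b][px]) - means[i, b]), tol)
    }
  }
})

test_that("nearest-centroid classification recovers the truth as noise vanishes", {
  cls <- default_classes(band_sd = 1e-4)
  cfg <- scene_config(height = 64, width = 64, classes = cls, noise_sd = 0, seed = 3)
  sc <- generate_scene(cfg)
  bm <- class_band_means(cls)
  X <- cbind(as.vector(sc$bands[, , 1]), as.vector(sc$bands[, , 2]),
             as.vector(sc$bands[, , 3]), as.vector(sc$bands[, , 4]))
  d2 <- outer(rowSums(X^2), rep(1, nrow(bm))) - 2 * X %*% t(bm) +
    outer(rep(1, nrow(X)), rowSums(bm^2))
  pred <- cls$class_id[max.col(-d2, ties.method = "first")]
  # lattice modulation (amplitude 0.02) slightly perturbs lattice classes
  expect_gt(mean(pred == as.vector(sc$truth_mask)), 0.999)
})

test_that("corruption identity, calibration and determinism hold", {
  sc <- generate_scene(scene_config(height = 256, width = 256, seed = 5))
  truth <- sc$truth_mask

  expect_identical(corrupt_annotations(truth, corruption_config()), truth)

  cc <- corruption_config(mislabel_fraction = 0.25, seed = 2)
  lab <- corrupt_annotations(truth, cc, n_classes = 15)
  frac <- mean(lab != truth)
  expect_gte(frac, 0.23)
  expect_lte(frac, 0.27)
  expect_true(all(lab >= 0 & lab <= 14))
  expect_identical(lab, corrupt_annotations(truth, cc, n_classes = 15))

  all_drop <- corrupt_annotations(truth, corruption_config(drop_fraction = 1))
  expect_true(all(all_drop == -1L))

  expect_error(corruption_config(mislabel_fraction = 1.3))
  expect_error(corruption_config(drop_fraction = -0.1))
})

test_that("boundary shift and polygon mixing perturb labels without inventing codes", {
  sc <- generate_scene(scene_config(height = 64, width = 64, seed = 9))
  lab <- corrupt_annotations(
    sc$truth_mask,
    corruption_config(boundary_shift_px = 3, polygon_mix_fraction = 0.5, seed = 4),
    n_classes = 15
  )
  expect_true(all(lab %in% 0:14))
  expect_gt(mean(lab != sc$truth_mask), 0) # something moved
  expect_equal(dim(lab), dim(sc$truth_mask))
})

test_that("dataset pools are disjoint, sized by the fractions, and reproducible", {
  pools <- tiny_pools(10, seed = 3)
  m <- pools$manifest
  expect_equal(sum(m$pool == "annotated"), 5)
  expect_equal(sum(m$pool == "test"), 2)
  expect_equal(sum(m$pool == "unannotated"), 3)
  expect_false(any(duplicated(m$scene_id)))
  expect_setequal(names(pools$labels), m$scene_id[m$pool == "annotated"])
  pools2 <- tiny_pools(10, seed = 3)
  expect_identical(pools$manifest, pools2$manifest)
  expect_error(generate_dataset(2, scene_config()), "at least 3")
})

test_that("pool partition counting follows floor arithmetic", {
  p <- partition_pools(100, annotated_fraction = 0.38, seed = 1)
  expect_equal(sum(p == "annotated"), 38)
  p <- partition_pools(10, annotated_fraction = 0.5, test_fraction = 0.2, seed = 1)
  expect_equal(as.integer(table(p)[c("annotated", "test", "unannotated")]),
               c(5L, 2L, 3L))
})
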