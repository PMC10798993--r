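test_that("band normalization handles fixed-range, min-max, and degenerate inputs", {
  x <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  expect_equal(normalize_bands(x, "fixed"), x)

  dn <- array(100, dim = c(2, 2, 1))
  dn[1, 1, 1] <- 100; dn[1, 2, 1] <- 300; dn[2, 1, 1] <- 200; dn[2, 2, 1] <- 150
  nm <- normalize_bands(dn, "minmax")
  expect_equal(nm[2, 1, 1], 0.5) # (200 - 100) / (300 - 100)
  expect_equal(range(nm), c(0, 1))

  const <- array(7, dim = c(4, 4, 2))
  expect_true(all(normalize_bands(const, "minmax") == 0))

  bad <- x; bad[1, 1, 1] <- -1
  expect_error(normalize_bands(bad), "negative")
  bad2 <- x; bad2[1, 1, 1] <- NaN
  expect_error(normalize_bands(bad2), "finite")
})

test_that("vegetation indices match their closed forms and guard zero denominators", {
  b <- array(0, dim = c(1, 1, 4))
  b[1, 1, ] <- c(0.1, 0.4, 0.2, 0.8) # blue, green, red, nir
  idx <- compute_indices(b)
  expect_equal(idx[1, 1, 1], 0.6)              # ndvi = (0.8-0.2)/(0.8+0.2)
  expect_equal(idx[1, 1, 2], (0.6 / 1.5) * 1.5) # savi = (0.8-0.2)/(1+0.5)*1.5
  expect_equal(idx[1, 1, 3], -1 / 3)           # ndmi = (0.4-0.8)/(0.4+0.8)

  eq <- array(0.3, dim = c(3, 3, 4))
  expect_true(all(compute_indices(eq)[, , 1] == 0)) # nir == red

  zero <- array(0, dim = c(3, 3, 4))
  expect_true(all(compute_indices(zero) == 0))
  expect_error(compute_indices(array(0, dim = c(2, 2, 3))), "4")
})

test_that("index computation is elementwise: permuting pixels permutes outputs", {
  withr::with_seed(1, {
    b <- array(runif(8 * 8 * 4), dim = c(8, 8, 4))
  })
  idx <- compute_indices(b)
  perm <- sample(64)
  bp <- array(0, dim = dim(b))
  for (ch in 1:4) bp[, , ch] <- matrix(as.vector(b[, , ch])[perm], 8, 8)
  idxp <- compute_indices(bp)
  for (ch in 1:3) {
    expect_equal(as.vector(idxp[, , ch]), as.vector(idx[, , ch])[perm])
  }
})

test_that("the 7-channel stack keeps the fixed channel order", {
  b <- array(runif(16 * 16 * 4), dim = c(16, 16, 4))
  st <- build_stack(b)
  expect_equal(dim(st), c(16, 16, 7))
  expect_equal(dimnames(st)[[3]], stack_channels())
  expect_equal(st[, , 1:4], b, ignore_attr = TRUE)
})

test_that("minimum-area filtering keeps components at the 3.8 ha threshold", {
  # at 5 m pixels, 3.8 ha = 38000 / 25 = 1520 pixels
  mask <- matrix(FALSE, 120, 120)
  mask[1:16, 1:95] <- TRUE   # 16 x 95 = 1520 px component: kept
  small <- matrix(FALSE, 120, 120)
  small[1:16, 1:95] <- TRUE
  small[16, 95] <- FALSE     # 1519 px: removed
  out_keep <- filter_min_patch(mask, pixel_size = 5)
  out_drop <- filter_min_patch(small, pixel_size = 5)
  expect_equal(sum(out_keep), 1520)
  expect_equal(sum(out_drop), 0)

  expect_equal(filter_min_patch(matrix(FALSE, 10, 10), 5), matrix(FALSE, 10, 10))
  giant <- matrix(TRUE, 130, 130) # one giant component, untouched
  expect_equal(filter_min_patch(giant, 5), giant)
  expect_error(filter_min_patch(mask, pixel_size = 0))
})

test_that("patch filtering is monotone in the area threshold and respects connectivity", {
  withr::with_seed(4, {
    mask <- matrix(runif(64 * 64) < 0.4, 64, 64)
  })
  a <- filter_min_patch(mask, 5, min_area_ha = 0.05)
  b <- filter_min_patch(mask, 5, min_area_ha = 0.2)
  expect_true(all(b <= a))         # raising the threshold never adds pixels
  expect_true(all(a <= mask))

  diagm <- matrix(FALSE, 6, 6)
  diagm[2, 2] <- TRUE
  diagm[3, 3] <- TRUE # touching diagonally only
  # 8-connected: one 2-px component; 4-connected: two 1-px components
  keep8 <- filter_min_patch(diagm, 100, min_area_ha = 2, connectivity = 8)
  keep4 <- filter_min_patch(diagm, 100, min_area_ha = 2, connectivity = 4)
  expect_equal(sum(keep8), 2)
  expect_equal(sum(keep4), 0)
})

test_that("connected-component labelling agrees with an independent 4-connected oracle", {
  skip_if_not_installed("EBImage")
  withr::with_seed(11, {
    mask <- matrix(runif(48 * 48) < 0.35, 48, 48)
  })
  ours <- lufor:::label_components(mask, connectivity = 4)
  ref <- EBImage::bwlabel(mask * 1)
  # same partition up to label permutation
  expect_equal(max(ours), max(ref))
  pairs <- unique(cbind(as.vector(ours), as.vector(ref)))
  pairs <- pairs[pairs[, 1] > 0, , drop = FALSE]
  expect_false(any(duplicated(pairs[, 1])))
  expect_false(any(duplicated(pairs[, 2])))
})

test_that("patch extraction tiles fully and reassembly restores the map", {
  st <- array(runif(256 * 256 * 7), dim = c(256, 256, 7))
  lab <- matrix(sample(0:14, 256 * 256, TRUE), 256, 256)
  tl <- extract_patches(st, lab, patch_size = 128, stride = 128)
  expect_length(tl$patches, 4)
  back <- reassemble_patches(tl, lapply(tl$patches, `[[`, "labels"))
  expect_equal(back, lab)

  one <- extract_patches(st, lab, patch_size = 256)
  expect_length(one$patches, 1)
  expect_equal(one$patches[[1]]$x, st, ignore_attr = TRUE)

  st2 <- st[1:250, 1:250, , drop = FALSE]
  lab2 <- lab[1:250, 1:250]
  tl2 <- extract_patches(st2, lab2, patch_size = 128, stride = 128)
  expect_length(tl2$patches, 4)
  back2 <- reassemble_patches(tl2, lapply(tl2$patches, `[[`, "labels"))
  expect_equal(dim(back2), c(250, 250))
  expect_equal(back2, lab2)

  expect_error(extract_patches(st, lab, patch_size = 300), "exceeds")
  expect_error(extract_patches(st, lab, patch_size = 64, stride = 0), "stride")
})
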