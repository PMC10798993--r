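test_that("the 80/20 split reproduces the reference pool counts", {
  sp <- split_pools(895, train_fraction = 0.8, seed = 1)
  expect_length(sp$train, 716)
  expect_length(sp$test, 179)
  expect_length(intersect(sp$train, sp$test), 0)

  sp2 <- split_pools(10, 0.5, seed = 2)
  expect_length(sp2$train, 5)
  expect_length(sp2$test, 5)

  sp3 <- split_pools(100, 0.38, seed = 3)
  expect_length(sp3$train, 38)
  expect_length(sp3$test, 62)

  expect_identical(split_pools(50, 0.8, seed = 9), split_pools(50, 0.8, seed = 9))
  expect_error(split_pools(100, 1.0), "between")
  expect_error(split_pools(1, 0.5), "at least 2")
})

test_that("pixel entropy matches its closed forms and bounds", {
  onehot <- array(0, dim = c(1, 1, 15))
  onehot[1, 1, 3] <- 1
  expect_equal(pixel_entropy(onehot)[1, 1], 0)

  unif <- array(1 / 15, dim = c(2, 2, 15))
  expect_equal(pixel_entropy(unif), matrix(log(15), 2, 2))

  half <- array(0.5, dim = c(1, 1, 2))
  expect_equal(pixel_entropy(half)[1, 1], log(2))

  pr <- random_probs(8, 8, 15, seed = 4)
  H <- pixel_entropy(pr)
  expect_true(all(H >= 0 & H <= log(15) + 1e-12))

  expect_error(pixel_entropy(array(0.9, dim = c(2, 2, 3))), "simplex")
})

test_that("image uncertainty aggregates and normalizes as documented", {
  k <- 15
  H <- matrix(0, 4, 4)
  expect_equal(image_uncertainty(H, k), 0)
  expect_equal(image_uncertainty(H, k, aggregation = "max"), 0)

  Hmax <- matrix(log(k), 4, 4)
  expect_equal(image_uncertainty(Hmax, k), 1)
  expect_equal(image_uncertainty(Hmax, k, entropy_scale = "nats"), log(k))

  Hhalf <- rbind(matrix(0, 2, 4), matrix(log(k), 2, 4))
  expect_equal(image_uncertainty(Hhalf, k), 0.5)
  expect_equal(image_uncertainty(Hhalf, k, aggregation = "max"), 1)
  expect_equal(image_uncertainty(Hhalf, k, aggregation = "fraction_above"), 0.5)

  # masking restricts the aggregation
  mask <- rbind(matrix(FALSE, 2, 4), matrix(TRUE, 2, 4))
  expect_equal(image_uncertainty(Hhalf, k, mask = mask), 1)
})

test_that("selection keeps exactly the scenes above the threshold", {
  pools <- tiny_pools(6, seed = 5)
  un <- pool_ids(pools, "unannotated")
  expect_length(un, 2)
  scores <- setNames(c(0.70, 0.50), un)
  sel <- select_for_annotation(pools, model = NULL, al_config(), scores = scores)
  expect_equal(sel$scene_id, un[1])

  scores2 <- setNames(c(0.61, 0.59), un)
  sel2 <- select_for_annotation(pools, NULL, al_config(entropy_threshold = 0.6),
                                scores = scores2)
  expect_equal(sel2$scene_id, un[1])

  # a uniform-probability model is maximally uncertain everywhere: select all
  m <- uniform_model()
  sel3 <- select_for_annotation(pools, m, al_config())
  expect_setequal(sel3$scene_id, un)
  expect_equal(sel3$uncertainty, rep(1, 2), tolerance = 1e-12)

  # a threshold at the entropy maximum selects nothing (strict inequality)
  sel4 <- select_for_annotation(pools, m,
                                al_config(entropy_threshold = log(15),
                                          entropy_scale = "nats"))
  expect_equal(nrow(sel4), 0)

  expect_error(al_config(entropy_threshold = 1.0), "< 1")
  expect_error(al_config(entropy_threshold = 0))
})

test_that("the simulated annotator moves scenes and reveals clean truth", {
  pools <- tiny_pools(8, seed = 6)
  un <- pool_ids(pools, "unannotated")
  ann0 <- pool_ids(pools, "annotated")
  test0 <- pool_ids(pools, "test")

  p1 <- simulated_annotator(pools, character(0))
  expect_identical(p1$manifest, pools$manifest)

  p2 <- simulated_annotator(pools, un, cycle = 1)
  expect_length(pool_ids(p2, "unannotated"), 0)
  expect_setequal(pool_ids(p2, "annotated"), c(ann0, un))
  expect_identical(pool_ids(p2, "test"), test0)
  # conservation of annotated + unannotated
  expect_equal(length(pool_ids(p2, "annotated")) + length(pool_ids(p2, "unannotated")),
               length(ann0) + length(un))
  # revealed labels are the clean truth
  for (id in un) expect_identical(p2$labels[[id]], p2$scenes[[id]]$truth_mask)
  expect_equal(unique(p2$manifest$cycle_of_annotation[p2$manifest$scene_id %in% un]), 1L)

  expect_error(simulated_annotator(pools, c(un[1], test0[1])), "not in the unannotated")
})

test_that("the loop produces one report per cycle with conserved pools", {
  pools <- tiny_pools(6, seed = 8, mislabel = 0.3, drop = 0.3)
  run <- run_al_loop(
    pools,
    mconfig = model_config(depth = 2, base_filters = 4, seed = 0),
    tconfig = train_config(epochs = 2, batch_size = 4, learning_rate = 3e-3,
                           patch_size = 32, seed = 0),
    aconfig = al_config(n_cycles = 1, seed = 0)
  )
  r <- run$reports
  expect_equal(r$cycle, 0:1)
  expect_true(all(diff(r$n_annotated) >= 0))
  expect_true(all(diff(r$n_unannotated) <= 0))
  expect_equal(unique(r$n_test), length(pool_ids(pools, "test")))
  expect_equal(r$n_annotated + r$n_unannotated,
               rep(r$n_annotated[1] + r$n_unannotated[1], nrow(r)))
  expect_true(all(run$per_class$cycle %in% 0:1))
  expect_s3_class(autoplot(run), "ggplot")
  g <- glance(run)
  expect_equal(g$improvement, g$final_macro_f1 - g$initial_macro_f1)

  run0 <- run_al_loop(
    pools,
    mconfig = model_config(depth = 2, base_filters = 4, seed = 0),
    tconfig = train_config(epochs = 1, batch_size = 4, patch_size = 32, seed = 0),
    aconfig = al_config(n_cycles = 0, seed = 0)
  )
  expect_equal(nrow(run0$reports), 1)
})
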