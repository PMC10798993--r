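test_that("the network preserves spatial dimensions and emits simplex probabilities", {
  m <- tiny_model()
  st <- array(runif(16 * 16 * 7), dim = c(16, 16, 7))
  probs <- predict_unet(m, st)
  expect_equal(dim(probs), c(16, 16, 15))
  expect_true(all(probs >= 0))
  expect_equal(apply(probs, c(1, 2), sum), matrix(1, 16, 16), tolerance = 1e-10)

  expect_error(predict_unet(m, st[, , 1:3]), "channels")
  expect_error(predict_unet(m, array(0, dim = c(10, 10, 7))), "divisible")
})

test_that("initialization is deterministic under a fixed seed", {
  st <- array(runif(8 * 8 * 7), dim = c(8, 8, 7))
  m1 <- tiny_model(seed = 42)
  m2 <- tiny_model(seed = 42)
  expect_identical(m1$params, m2$params)
  expect_identical(predict_unet(m1, st), predict_unet(m2, st))
})

test_that("attention gates emit coefficients in [0, 1]", {
  m <- tiny_model(seed = 3)
  X <- matrix(runif(16 * 16 * 7), 16 * 16, 7)
  fw <- lufor:::unet_forward(m, X, 16, 16, 1, training = FALSE)
  for (l in seq_along(fw$tape$att)) {
    a <- fw$tape$att[[l]]$a
    expect_true(all(a >= 0 & a <= 1))
    expect_gt(stats::sd(a), 0) # gates actually modulate
  }
})

test_that("focal loss matches its closed forms", {
  # perfect prediction with probability 1 -> loss 0
  k <- 4
  probs <- array(0, dim = c(2, 2, k))
  t <- matrix(c(0L, 1L, 2L, 3L), 2, 2)
  for (i in 1:2) for (j in 1:2) probs[i, j, t[i, j] + 1] <- 1
  expect_equal(focal_loss(probs, t, focal_params(n_classes = k)), 0)

  # single pixel, p_t = 0.5, gamma = 2: 0.25 * ln 2
  p1 <- array(c(0.5, 0.5), dim = c(1, 1, 2))
  expect_equal(focal_loss(p1, matrix(0L, 1, 1), focal_params(n_classes = 2, gamma = 2)),
               0.25 * log(2))

  # gamma = 0, unit alpha and weights reduces to mean cross-entropy
  pr <- random_probs(16, 16, 5, seed = 3)
  tt <- matrix(sample(0:4, 256, TRUE), 16, 16)
  fl <- focal_loss(pr, tt, focal_params(n_classes = 5, gamma = 0))
  pmat <- matrix(pr, 256, 5)
  ce <- mean(-log(pmat[cbind(1:256, as.vector(tt) + 1)]))
  expect_equal(fl, ce, tolerance = 1e-9)

  # ignored pixels contribute exactly zero
  tt2 <- tt
  tt2[1:8, ] <- -1L
  fl2 <- focal_loss(pr, tt2, focal_params(n_classes = 5, gamma = 0))
  keep <- as.vector(row(tt) > 8)
  ce2 <- mean(-log(pmat[cbind(which(keep), as.vector(tt)[keep] + 1)]))
  expect_equal(fl2, ce2, tolerance = 1e-9)

  expect_error(focal_loss(pr, matrix(9L, 16, 16), focal_params(n_classes = 5)), "0..K-1")
  expect_error(focal_loss(pr, matrix(-1L, 16, 16), focal_params(n_classes = 5)), "ignored")
})

test_that("focal loss is non-increasing in gamma at fixed confidence", {
  pr <- random_probs(8, 8, 3, seed = 9)
  tt <- matrix(sample(0:2, 64, TRUE), 8, 8)
  gammas <- c(0, 0.5, 1, 2, 4)
  losses <- vapply(gammas, function(g) {
    focal_loss(pr, tt, focal_params(n_classes = 3, gamma = g))
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("the analytic gradient of the loss matches finite differences", {
  set.seed(21)
  mc <- model_config(n_channels = 3, n_classes = 3, depth = 1, base_filters = 3,
                     dropout_rate = 0, seed = 5)
  m <- build_unet(mc)
  H <- 4; W <- 4; B <- 1
  X <- matrix(runif(H * W * 3), H * W, 3)
  t <- sample(c(-1L, 0:2), H * W, replace = TRUE)
  fp <- focal_params(n_classes = 3, gamma = 2, alpha = c(1, 2, 0.5))
  loss_at <- function(m) {
    bn <- m$bn
    fw <- lufor:::unet_forward(m, X, H, W, B, training = TRUE)
    m$bn <- bn
    P <- lufor:::softmax_rows(fw$logits)
    lufor:::focal_grad_logits(P, t, fp)$loss
  }
  bn <- m$bn
  fw <- lufor:::unet_forward(m, X, H, W, B, training = TRUE)
  m$bn <- bn
  P <- lufor:::softmax_rows(fw$logits)
  fg <- lufor:::focal_grad_logits(P, t, fp)
  grads <- lufor:::unet_backward(m, fw$tape, fg$dZ)
  eps <- 1e-5
  for (nm in c("enc1_c1_W", "att1_Wx", "att1_psi", "dec1_c2_W", "head_W", "bot_c1_g")) {
    p0 <- m$params[[nm]]
    idx <- sample(length(p0), min(3, length(p0)))
    for (i in idx) {
      m$params[[nm]][i] <- p0[i] + eps
      lp <- loss_at(m)
      m$params[[nm]][i] <- p0[i] - eps
      lm <- loss_at(m)
      m$params[[nm]][i] <- p0[i]
      expect_equal(grads[[nm]][i], (lp - lm) / (2 * eps), tolerance = 1e-4)
    }
  }
})

test_that("training runs, records history, reduces the loss, and is reproducible", {
  pools <- tiny_pools(4, seed = 13)
  patches <- pools_to_patches(pools, patch_size = 32)
  mc <- model_config(depth = 2, base_filters = 6, seed = 1)
  tc <- train_config(epochs = 6, batch_size = 4, learning_rate = 3e-3,
                     patch_size = 32, seed = 2)

  m1 <- build_unet(mc)
  train_unet(m1, patches, tc)
  expect_equal(nrow(m1$history), 6)
  expect_lt(tail(m1$history$loss, 1), m1$history$loss[1])

  m2 <- build_unet(mc)
  train_unet(m2, patches, tc)
  expect_identical(m1$history, m2$history)

  m3 <- build_unet(mc)
  one <- train_config(epochs = 1, batch_size = 4, patch_size = 32, seed = 2)
  train_unet(m3, patches[1], one)
  expect_equal(nrow(m3$history), 1)

  expect_error(train_unet(build_unet(mc), list(), tc), "empty")
  allig <- list(list(x = patches[[1]]$x, labels = matrix(-1L, 32, 32)))
  expect_error(train_unet(build_unet(mc), allig, tc), "ignored")
})

test_that("argmax maps break ties to the lowest class and honour the loss mask", {
  probs <- array(0, dim = c(2, 2, 3))
  probs[1, 1, ] <- c(0.2, 0.8, 0)
  probs[1, 2, ] <- c(0.5, 0.5, 0)  # tie -> class 0
  probs[2, 1, ] <- c(0.1, 0.2, 0.7)
  probs[2, 2, ] <- c(1 / 3, 1 / 3, 1 / 3) # three-way tie -> class 0
  cm <- argmax_map(probs)
  expect_equal(cm, matrix(c(1L, 2L, 0L, 0L), 2, 2))

  none <- argmax_map(probs, loss_mask = matrix(FALSE, 2, 2))
  expect_true(all(none == 255L))
  some <- argmax_map(probs, loss_mask = matrix(c(TRUE, FALSE, FALSE, TRUE), 2, 2))
  expect_equal(some[1, 1], 1L)
  expect_equal(some[2, 1], 255L)
})

test_that("model snapshots round-trip through a plain list", {
  m <- tiny_model(seed = 8)
  st <- array(runif(8 * 8 * 7), dim = c(8, 8, 7))
  p0 <- predict_unet(m, st)
  lst <- lufor:::unet_to_list(m)
  m2 <- lufor:::unet_from_list(lst)
  expect_equal(predict_unet(m2, st), p0)
})
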