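#' Segmentation model configuration
#'
#' A compact attention U-Net: `depth` encoder levels of two 3x3
#' convolutions (same padding) with BatchNorm and ReLU, 2x2 max pooling, a
#' bottleneck block, and a mirrored decoder whose skip connections pass
#' through additive attention gates before concatenation. The output head is
#' a 1x1 convolution to `n_classes` logits with a per-pixel softmax. Dropout
#' is applied after each convolution block during training.
#'
#' @param n_channels Input channels (7: four bands plus ndvi, savi, ndmi).
#' @param n_classes Number of output classes K.
#' @param depth Encoder levels (>= 1); input height/width must be divisible
#'   by `2^depth`.
#' @param base_filters Filters at the first level; doubled per level.
#' @param dropout_rate Dropout probability in \[0, 1).
#' @param batch_norm Use BatchNorm between convolutions and nonlinearity.
#' @param seed Seed for the (He-normal) weight initialization.
#' @return A list of class `lufor_model_config`.
#' @export
model_config <- function(n_channels = 7L, n_classes = 15L, depth = 3L,
                         base_filters = 16L, dropout_rate = 0.1,
                         batch_norm = TRUE, seed = 0L) {
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  if (dropout_rate < 0 || dropout_rate >= 1) stop("dropout_rate must lie in [0, 1)", call. = FALSE)
  structure(list(
    n_channels = as.integer(n_channels), n_classes = as.integer(n_classes),
    depth = as.integer(depth), base_filters = as.integer(base_filters),
    dropout_rate = dropout_rate, batch_norm = isTRUE(batch_norm),
    seed = as.integer(seed)
  ), class = "lufor_model_config")
}

#' Training configuration
#'
#' Defaults follow the reference training recipe (200 epochs, batch size 64,
#' Adam with learning rate 1e-4). For CPU-scale experiments the package's
#' benchmark configurations use fewer epochs, smaller batches and a larger
#' learning rate; see the methods vignette.
#'
#' @param epochs Training epochs.
#' @param batch_size Patches per optimization step.
#' @param learning_rate Adam learning rate.
#' @param patch_size,stride Patch tiling applied to training scenes.
#' @param patches_per_epoch Optional cap on the number of (randomly sampled,
#'   without replacement) patches visited per epoch, decoupling epoch cost
#'   from pool size; NULL visits every patch.
#' @param seed Seed controlling shuffling and dropout.
#' @export
train_config <- function(epochs = 200L, batch_size = 64L, learning_rate = 1e-4,
                         patch_size = 64L, stride = patch_size,
                         patches_per_epoch = NULL, seed = 0L) {
  stopifnot(epochs >= 1, batch_size >= 1, learning_rate > 0, patch_size >= 8)
  structure(list(
    epochs = as.integer(epochs), batch_size = as.integer(batch_size),
    learning_rate = learning_rate, patch_size = as.integer(patch_size),
    stride = as.integer(stride),
    patches_per_epoch = if (is.null(patches_per_epoch)) NULL else as.integer(patches_per_epoch),
    seed = as.integer(seed)
  ), class = "lufor_train_config")
}

#' Focal loss parameters
#'
#' The focal loss down-weights well-classified pixels via the modulating
#' factor `(1 - p)^gamma` and re-balances classes via `alpha` and per-class
#' weights: for a pixel of true class t with predicted probability p,
#' `FL = -class_weights[t] * alpha[t] * (1 - p)^gamma * log(p)`.
#' Pixels labeled `ignore_label` contribute exactly zero.
#'
#' @param n_classes Number of classes K.
#' @param alpha Per-class alpha, recycled to length K.
#' @param gamma Focusing exponent, >= 0; 0 recovers weighted cross-entropy.
#' @param class_weights Per-class multiplier, recycled to length K, or NULL
#'   (default) to compute clipped inverse-frequency weights from the
#'   training labels at fit time. [focal_loss()] treats NULL as unit
#'   weights.
#' @param ignore_label Label code excluded from the loss (default -1).
#' @export
focal_params <- function(n_classes = 15L, alpha = 1, gamma = 2,
                         class_weights = NULL, ignore_label = -1L) {
  if (gamma < 0) stop("gamma must be >= 0", call. = FALSE)
  alpha <- rep_len(alpha, n_classes)
  if (!is.null(class_weights)) class_weights <- rep_len(class_weights, n_classes)
  if (any(alpha <= 0)) stop("alpha must be positive", call. = FALSE)
  structure(list(
    n_classes = as.integer(n_classes), alpha = alpha, gamma = gamma,
    class_weights = class_weights, ignore_label = as.integer(ignore_label)
  ), class = "lufor_focal_params")
}

unet_filters <- function(config) {
  f <- config$base_filters * 2^(seq_len(config$depth) - 1)
  list(enc = as.integer(f), bottleneck = as.integer(config$base_filters * 2^config$depth))
}

he_init <- function(nin, nout) {
  matrix(rnorm(nin * nout, 0, sqrt(2 / nin)), nin, nout)
}

new_conv_block_params <- function(params, name, cin, cout) {
  for (i in 1:2) {
    ci <- if (i == 1) cin else cout
    params[[paste0(name, "_c", i, "_W")]] <- he_init(9L * ci, cout)
    params[[paste0(name, "_c", i, "_b")]] <- numeric(cout)
    params[[paste0(name, "_c", i, "_g")]] <- rep(1, cout)
    params[[paste0(name, "_c", i, "_beta")]] <- numeric(cout)
  }
  params
}

#' Build an attention U-Net
#'
#' Initializes all weights (He-normal, deterministically from
#' `config$seed`) and returns a mutable model handle. The network preserves
#' spatial dimensions for any input whose height and width are divisible by
#' `2^depth`.
#'
#' @param config A [model_config()].
#' @return A model handle of class `lufor_unet` (an environment holding
#'   parameters, BatchNorm running statistics, optimizer state and training
#'   history).
#' @export
build_unet <- function(config) {
  stopifnot(inherits(config, "lufor_model_config"))
  fl <- unet_filters(config)
  d <- config$depth
  params <- list()
  bn <- list()
  withr::with_seed(config$seed, {
    cin <- config$n_channels
    for (l in seq_len(d)) {
      params <- new_conv_block_params(params, paste0("enc", l), cin, fl$enc[l])
      cin <- fl$enc[l]
    }
    params <- new_conv_block_params(params, "bot", cin, fl$bottleneck)
    cup <- fl$bottleneck
    for (l in rev(seq_len(d))) {
      cs <- fl$enc[l]
      ci <- max(cs %/% 2L, 4L)
      params[[paste0("att", l, "_Wx")]] <- he_init(cs, ci)
      params[[paste0("att", l, "_Wg")]] <- he_init(cup, ci)
      params[[paste0("att", l, "_b1")]] <- numeric(ci)
      params[[paste0("att", l, "_psi")]] <- he_init(ci, 1L)
      params[[paste0("att", l, "_b2")]] <- numeric(1)
      params <- new_conv_block_params(params, paste0("dec", l), cup + cs, cs)
      cup <- cs
    }
    params[["head_W"]] <- he_init(fl$enc[1], config$n_classes)
    params[["head_b"]] <- numeric(config$n_classes)
  })
  for (nm in names(params)) {
    if (grepl("_g$", nm)) {
      base <- sub("_g$", "", nm)
      bn[[base]] <- list(mean = numeric(length(params[[nm]])), var = rep(1, length(params[[nm]])))
    }
  }
  model <- new.env(parent = emptyenv())
  model$params <- params
  model$bn <- bn
  model$config <- config
  model$adam <- NULL
  model$history <- tibble::tibble(epoch = integer(), loss = numeric())
  class(model) <- "lufor_unet"
  model
}

#' @export
print.lufor_unet <- function(x, ...) {
  np <- sum(vapply(x$params, length, numeric(1)))
  cat(sprintf("<lufor_unet> depth %d, base %d, %d classes, %s parameters, %d epochs trained\n",
              x$config$depth, x$config$base_filters, x$config$n_classes,
              format(np, big.mark = ","), nrow(x$history)))
  invisible(x)
}

# ---- forward / backward -----------------------------------------------------

conv_block_forward <- function(model, name, X, H, W, B, training) {
  p <- model$params
  sinfo <- conv_shift_info(H, W, B)
  cache <- list(name = name, sinfo = sinfo, N = nrow(X))
  cur <- X
  for (i in 1:2) {
    pre <- paste0(name, "_c", i)
    cv <- conv2d_forward(cur, p[[paste0(pre, "_W")]], p[[paste0(pre, "_b")]], sinfo)
    cache[[paste0("Xin", i)]] <- cur
    if (model$config$batch_norm) {
      bnr <- bn_forward(cv$Y, p[[paste0(pre, "_g")]], p[[paste0(pre, "_beta")]],
                        model$bn[[pre]], training)
      if (training) model$bn[[pre]] <- bnr$running
      cache[[paste0("bn", i)]] <- bnr[c("xhat", "istd")]
      act <- bnr$Y
    } else {
      act <- cv$Y
    }
    rl <- relu_forward(act)
    cache[[paste0("relu", i)]] <- rl$mask
    cur <- rl$Y
  }
  dr <- model$config$dropout_rate
  if (training && dr > 0) {
    mask <- matrix(runif(length(cur)) >= dr, nrow(cur), ncol(cur)) / (1 - dr)
    cache$dropout <- mask
    cur <- cur * mask
  }
  cache$Y <- cur
  cache
}

conv_block_backward <- function(model, cache, dY, grads) {
  p <- model$params
  name <- cache$name
  if (!is.null(cache$dropout)) dY <- dY * cache$dropout
  for (i in 2:1) {
    pre <- paste0(name, "_c", i)
    dY <- dY * cache[[paste0("relu", i)]]
    if (model$config$batch_norm) {
      bb <- bn_backward(dY, cache[[paste0("bn", i)]], p[[paste0(pre, "_g")]])
      grads[[paste0(pre, "_g")]] <- bb$dgamma
      grads[[paste0(pre, "_beta")]] <- bb$dbeta
      dY <- bb$dX
    }
    cb <- conv2d_backward(dY, cache[[paste0("Xin", i)]], p[[paste0(pre, "_W")]],
                          cache$sinfo)
    grads[[paste0(pre, "_W")]] <- cb$dW
    grads[[paste0(pre, "_b")]] <- cb$db
    dY <- cb$dX
  }
  list(dX = dY, grads = grads)
}

attention_forward <- function(model, l, Xs, G, Hs, Ws, B) {
  p <- model$params
  uidx <- upsample_indices(Hs %/% 2L, Ws %/% 2L, B)
  Gu <- upsample_forward(G, uidx)
  U <- Xs %*% p[[paste0("att", l, "_Wx")]] +
    Gu %*% p[[paste0("att", l, "_Wg")]] +
    rep(p[[paste0("att", l, "_b1")]], each = nrow(Xs))
  rl <- relu_forward(U)
  S <- rl$Y %*% p[[paste0("att", l, "_psi")]] + p[[paste0("att", l, "_b2")]]
  a <- sigmoid(S)
  list(Y = Xs * as.vector(a), a = a, q = rl$Y, relu_mask = rl$mask,
       Xs = Xs, Gu = Gu, uidx = uidx)
}

attention_backward <- function(model, l, cache, dY, grads, N_g) {
  p <- model$params
  a <- as.vector(cache$a)
  dXs <- dY * a
  da <- rowSums(dY * cache$Xs)
  ds <- da * a * (1 - a)
  grads[[paste0("att", l, "_psi")]] <- crossprod(cache$q, ds)
  grads[[paste0("att", l, "_b2")]] <- sum(ds)
  dq <- tcrossprod(ds, p[[paste0("att", l, "_psi")]])
  du <- dq * cache$relu_mask
  grads[[paste0("att", l, "_Wx")]] <- crossprod(cache$Xs, du)
  grads[[paste0("att", l, "_Wg")]] <- crossprod(cache$Gu, du)
  grads[[paste0("att", l, "_b1")]] <- colSums(du)
  dXs <- dXs + tcrossprod(du, p[[paste0("att", l, "_Wx")]])
  dGu <- tcrossprod(du, p[[paste0("att", l, "_Wg")]])
  dG <- upsample_backward(dGu, cache$uidx, N_g)
  list(dXs = dXs, dG = dG, grads = grads)
}

unet_forward <- function(model, X, H, W, B, training = FALSE) {
  cfg <- model$config
  d <- cfg$depth
  if (H %% 2^d != 0 || W %% 2^d != 0) {
    stop("input height/width must be divisible by 2^depth", call. = FALSE)
  }
  tape <- list(enc = vector("list", d), pool = vector("list", d),
               att = vector("list", d), dec = vector("list", d),
               dims = list())
  cur <- X
  curH <- H; curW <- W
  for (l in seq_len(d)) {
    blk <- conv_block_forward(model, paste0("enc", l), cur, curH, curW, B, training)
    tape$enc[[l]] <- blk
    tape$dims[[l]] <- c(curH, curW)
    pidx <- pool_indices(curH, curW, B)
    pl <- maxpool_forward(blk$Y, pidx)
    tape$pool[[l]] <- list(argmax = pl$argmax, pidx = pidx, N_in = nrow(blk$Y))
    cur <- pl$Y
    curH <- curH %/% 2L
    curW <- curW %/% 2L
  }
  bot <- conv_block_forward(model, "bot", cur, curH, curW, B, training)
  tape$bot <- bot
  D <- bot$Y
  for (l in rev(seq_len(d))) {
    dm <- tape$dims[[l]]
    att <- attention_forward(model, l, tape$enc[[l]]$Y, D, dm[1], dm[2], B)
    tape$att[[l]] <- att
    U <- upsample_forward(D, att$uidx)
    Z <- cbind(U, att$Y)
    tape$cup <- ncol(U)
    dec <- conv_block_forward(model, paste0("dec", l), Z, dm[1], dm[2], B, training)
    tape$dec[[l]] <- dec
    tape$dec[[l]]$cup <- ncol(U)
    tape$dec[[l]]$N_g <- nrow(D)
    D <- dec$Y
  }
  logits <- D %*% model$params$head_W + rep(model$params$head_b, each = nrow(D))
  tape$D1 <- D
  list(logits = logits, tape = tape)
}

unet_backward <- function(model, tape, dlogits) {
  d <- model$config$depth
  grads <- list()
  grads$head_W <- crossprod(tape$D1, dlogits)
  grads$head_b <- colSums(dlogits)
  dD <- tcrossprod(dlogits, model$params$head_W)
  dEnc <- vector("list", d)
  for (l in seq_len(d)) {
    cb <- conv_block_backward(model, tape$dec[[l]], dD, grads)
    grads <- cb$grads
    cup <- tape$dec[[l]]$cup
    dU <- cb$dX[, seq_len(cup), drop = FALSE]
    dAtt <- cb$dX[, (cup + 1):ncol(cb$dX), drop = FALSE]
    ab <- attention_backward(model, l, tape$att[[l]], dAtt, grads, tape$dec[[l]]$N_g)
    grads <- ab$grads
    dG <- ab$dG + upsample_backward(dU, tape$att[[l]]$uidx, tape$dec[[l]]$N_g)
    dEnc[[l]] <- ab$dXs
    dD <- dG
  }
  cb <- conv_block_backward(model, tape$bot, dD, grads)
  grads <- cb$grads
  dPool <- cb$dX
  for (l in rev(seq_len(d))) {
    pl <- tape$pool[[l]]
    dE <- maxpool_backward(dPool, pl$argmax, pl$pidx, pl$N_in) + dEnc[[l]]
    cb <- conv_block_backward(model, tape$enc[[l]], dE, grads)
    grads <- cb$grads
    dPool <- cb$dX
  }
  grads
}

# ---- focal loss -------------------------------------------------------------

#' Focal loss of a probability map against target labels
#'
#' Mean over non-ignored pixels of
#' `-class_weights[t] * alpha[t] * (1 - p_t)^gamma * log(p_t)`.
#' With `gamma = 0`, unit alpha and unit weights this is the mean
#' cross-entropy. Returns 0 when every non-ignored pixel is predicted with
#' probability 1.
#'
#' @param probs H x W x K probability array (or N x K matrix), rows on the
#'   simplex.
#' @param targets H x W integer matrix (or N vector) with codes in
#'   `{ignore_label} U 0..K-1`.
#' @param params A [focal_params()].
#' @return Nonnegative scalar.
#' @export
focal_loss <- function(probs, targets, params = focal_params(n_classes = dim_k(probs))) {
  P <- as_prob_matrix(probs)
  t <- as.integer(targets)
  if (length(t) != nrow(P)) stop("targets do not match probability map", call. = FALSE)
  bad <- t != params$ignore_label & (t < 0 | t >= params$n_classes)
  if (any(bad)) stop("target codes outside 0..K-1", call. = FALSE)
  valid <- t != params$ignore_label
  if (!any(valid)) stop("all pixels ignored", call. = FALSE)
  idx <- which(valid)
  pt <- P[cbind(idx, t[idx] + 1L)]
  cw <- params$class_weights
  if (is.null(cw)) cw <- rep(1, params$n_classes)
  w <- cw[t[idx] + 1L] * params$alpha[t[idx] + 1L]
  pt_c <- pmax(pt, 1e-12)
  mean_contrib <- w * (1 - pt)^params$gamma * (-log(pt_c))
  sum(mean_contrib) / length(idx)
}

dim_k <- function(probs) {
  d <- dim(probs)
  as.integer(d[length(d)])
}

as_prob_matrix <- function(probs) {
  d <- dim(probs)
  if (length(d) == 3) {
    matrix(probs, d[1] * d[2], d[3])
  } else if (length(d) == 2) {
    probs
  } else {
    stop("probs must be H x W x K or N x K", call. = FALSE)
  }
}

# gradient of the mean focal loss w.r.t. logits (softmax inputs)
focal_grad_logits <- function(P, t, params) {
  n <- nrow(P)
  valid <- t != params$ignore_label
  idx <- which(valid)
  nv <- length(idx)
  dZ <- matrix(0, n, ncol(P))
  if (nv == 0) return(list(dZ = dZ, loss = 0))
  ti <- t[idx] + 1L
  pt <- pmin(pmax(P[cbind(idx, ti)], 1e-12), 1 - 1e-12)
  cw <- params$class_weights
  if (is.null(cw)) cw <- rep(1, params$n_classes)
  w <- cw[ti] * params$alpha[ti]
  g <- params$gamma
  omp <- 1 - pt
  loss <- sum(w * omp^g * (-log(pt))) / nv
  term <- if (g == 0) 0 else g * omp^(g - 1) * log(pt)
  dldp <- w * (term - omp^g / pt) / nv
  cvec <- dldp * pt
  dZ[idx, ] <- -cvec * P[idx, , drop = FALSE]
  dZ[cbind(idx, ti)] <- dZ[cbind(idx, ti)] + cvec
  list(dZ = dZ, loss = loss)
}

# ---- training / prediction --------------------------------------------------

# Inverse-frequency class weights normalized to mean 1 over observed
# classes, clipped to [1/clip, clip] (and renormalized). Unclipped ratios of
# 100x between a dominant background and a rare class make the model swallow
# the background with the rare class; bounding the ratio keeps the
# re-balancing without that pathology.
inverse_frequency_weights <- function(labels, n_classes, ignore_label = -1L,
                                      clip = 2) {
  v <- unlist(lapply(labels, as.vector), use.names = FALSE)
  v <- v[v != ignore_label]
  counts <- tabulate(v + 1L, nbins = n_classes)
  w <- ifelse(counts > 0, 1 / counts, 0)
  pos <- w > 0
  if (any(pos)) {
    w[pos] <- w[pos] / mean(w[pos])
    w[pos] <- pmin(pmax(w[pos], 1 / clip), clip)
    w[pos] <- w[pos] / mean(w[pos])
  }
  w[!pos] <- 1
  w
}

#' Train the attention U-Net on annotated patches
#'
#' Stochastic mini-batch training with Adam on the focal loss. Unlabeled
#' pixels (code -1) are excluded from the loss, so corrupted annotations
#' with missing labels never teach the model a fake class. Fully seeded:
#' shuffling, dropout and initialization are reproducible.
#'
#' @param model A model handle from [build_unet()] (modified in place and
#'   returned).
#' @param patches List of training patches, each `list(x = H x W x C array,
#'   labels = H x W integer matrix)`; build them with [pools_to_patches()] or
#'   [extract_patches()].
#' @param config A [train_config()].
#' @param loss_params A [focal_params()]; if its `class_weights` are NULL or
#'   a single 1, inverse-frequency weights (normalized to mean 1) are
#'   computed from the training labels.
#' @param verbose Print per-epoch loss.
#' @return The model, with `model$history` holding one row per epoch.
#' @export
train_unet <- function(model, patches, config = train_config(),
                       loss_params = focal_params(n_classes = model$config$n_classes),
                       verbose = FALSE) {
  stopifnot(inherits(model, "lufor_unet"), inherits(config, "lufor_train_config"))
  if (length(patches) == 0) stop("empty training pool", call. = FALSE)
  labs <- lapply(patches, `[[`, "labels")
  if (all(vapply(labs, function(l) all(l == loss_params$ignore_label), logical(1)))) {
    stop("all training labels are ignored", call. = FALSE)
  }
  if (is.null(loss_params$class_weights)) {
    loss_params$class_weights <- inverse_frequency_weights(
      labs, model$config$n_classes, loss_params$ignore_label)
  }
  ps <- dim(patches[[1]]$x)[1]
  if (is.null(model$adam)) {
    model$adam <- lapply(model$params, function(p) list(m = p * 0, v = p * 0, t = 0))
  }
  Xmats <- lapply(patches, function(p) matrix(p$x, ps * ps, dim(p$x)[3]))
  tvecs <- lapply(patches, function(p) as.integer(p$labels))
  withr::with_seed(config$seed, {
    n <- length(patches)
    for (epoch in seq_len(config$epochs)) {
      ord <- sample(n)
      if (!is.null(config$patches_per_epoch)) {
        ord <- ord[seq_len(min(config$patches_per_epoch, n))]
      }
      n_epoch <- length(ord)
      losses <- c()
      for (start in seq(1, n_epoch, by = config$batch_size)) {
        take <- ord[start:min(start + config$batch_size - 1, n_epoch)]
        B <- length(take)
        X <- do.call(rbind, Xmats[take])
        t <- unlist(tvecs[take], use.names = FALSE)
        fw <- unet_forward(model, X, ps, ps, B, training = TRUE)
        P <- softmax_rows(fw$logits)
        fg <- focal_grad_logits(P, t, loss_params)
        losses <- c(losses, fg$loss)
        grads <- unet_backward(model, fw$tape, fg$dZ)
        for (nm in names(model$params)) {
          st <- adam_step(model$params[[nm]], grads[[nm]], model$adam[[nm]],
                          config$learning_rate)
          model$params[[nm]] <- st$param
          model$adam[[nm]] <- st$state
        }
      }
      model$history <- dplyr::bind_rows(
        model$history,
        tibble::tibble(epoch = nrow(model$history) + 1L, loss = mean(losses))
      )
      if (verbose) message(sprintf("epoch %d  loss %.5f", epoch, mean(losses)))
    }
  })
  invisible(model)
}

#' Predict per-pixel class probabilities for a stack
#'
#' @param model A trained `lufor_unet`.
#' @param stack H x W x C image stack matching the model's channel contract;
#'   H and W must be divisible by `2^depth`.
#' @return H x W x K probability array of class `lufor_probmap` (per-pixel
#'   softmax, rows on the simplex).
#' @export
predict_unet <- function(model, stack) {
  d <- dim(stack)
  if (length(d) != 3 || d[3] != model$config$n_channels) {
    stop("stack channels do not match the model", call. = FALSE)
  }
  X <- matrix(stack, d[1] * d[2], d[3])
  fw <- unet_forward(model, X, d[1], d[2], 1L, training = FALSE)
  P <- softmax_rows(fw$logits)
  out <- array(P, dim = c(d[1], d[2], model$config$n_classes))
  class(out) <- c("lufor_probmap", class(out))
  out
}

#' Hard class map from a probability map
#'
#' Per-pixel argmax; exact ties resolve to the lowest class id. When a
#' `loss_mask` is supplied only loss pixels receive a class; all other
#' pixels get the reserved no-data code.
#'
#' @param probs H x W x K probability array.
#' @param loss_mask Optional logical matrix restricting the emitted map.
#' @param nodata No-data code for non-loss pixels (default 255).
#' @return H x W integer class map.
#' @export
argmax_map <- function(probs, loss_mask = NULL, nodata = 255L) {
  d <- dim(probs)
  P <- as_prob_matrix(probs)
  cls <- max.col(P, ties.method = "first") - 1L
  out <- matrix(as.integer(cls), d[1], d[2])
  if (!is.null(loss_mask)) {
    if (!all(dim(loss_mask) == d[1:2])) stop("loss_mask shape mismatch", call. = FALSE)
    out[!loss_mask] <- as.integer(nodata)
  }
  out
}

#' Cut the annotated pool of a dataset into training patches
#'
#' @param pools A `lufor_pools` object.
#' @param patch_size,stride Tiling parameters.
#' @param ids Scene ids to use (default: the annotated pool).
#' @return List of `list(x, labels)` patches.
#' @export
pools_to_patches <- function(pools, patch_size = 64L, stride = patch_size,
                             ids = pool_ids(pools, "annotated")) {
  out <- list()
  for (id in ids) {
    sc <- pools$scenes[[id]]
    stk <- build_stack(sc$bands)
    lab <- pools$labels[[id]]
    if (is.null(lab)) lab <- sc$truth_mask
    tl <- extract_patches(stk, lab, patch_size, stride)
    out <- c(out, lapply(tl$patches, function(p) list(x = p$x, labels = p$labels)))
  }
  out
}

#' @export
tidy.lufor_unet <- function(x, ...) {
  x$history
}

#' @export
glance.lufor_unet <- function(x, ...) {
  tibble::tibble(
    depth = x$config$depth,
    base_filters = x$config$base_filters,
    n_classes = x$config$n_classes,
    n_parameters = sum(vapply(x$params, length, numeric(1))),
    epochs_trained = nrow(x$history),
    final_loss = if (nrow(x$history) > 0) tail(x$history$loss, 1) else NA_real_
  )
}

# serializable snapshot of a model (plain list, no environments)
unet_to_list <- function(model) {
  list(params = model$params, bn = model$bn, config = unclass(model$config),
       history = model$history)
}

unet_from_list <- function(lst) {
  model <- build_unet(do.call(model_config, lst$config[names(lst$config) != "class"]))
  model$params <- lst$params
  model$bn <- lst$bn
  model$history <- lst$history
  model
}
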