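#' Active-learning configuration
#'
#' Pool-based uncertainty sampling: after each training round, every
#' unannotated image is scored by the entropy of the model's class
#' probabilities and images scoring strictly above `entropy_threshold` are
#' sent to the annotator. With K classes the maximum per-pixel entropy is
#' `log(K)` nats; on the default `"normalized"` scale scores are divided by
#' `log(K)` so the threshold lives in (0, 1). The raw `"nats"` scale is also
#' available.
#'
#' @param entropy_threshold Selection threshold (strictly greater-than);
#'   default 0.6.
#' @param entropy_scale `"normalized"` (entropy / log K) or `"nats"`.
#' @param aggregation How per-pixel entropies become one image score:
#'   `"mean"` (default), `"max"`, or `"fraction_above"` (the fraction of
#'   pixels whose own entropy exceeds the threshold).
#' @param n_cycles Number of active-learning rounds after the initial
#'   training (default 2).
#' @param loss_pixels_only Score entropy over forest-loss pixels only when a
#'   loss mask is available (default TRUE).
#' @param seed Seed for the per-cycle retraining.
#' @export
al_config <- function(entropy_threshold = 0.6,
                      entropy_scale = c("normalized", "nats"),
                      aggregation = c("mean", "max", "fraction_above"),
                      n_cycles = 2L, loss_pixels_only = TRUE, seed = 0L) {
  entropy_scale <- match.arg(entropy_scale)
  aggregation <- match.arg(aggregation)
  if (entropy_threshold <= 0) stop("entropy_threshold must be positive", call. = FALSE)
  if (entropy_scale == "normalized" && entropy_threshold >= 1) {
    stop("normalized threshold must be < 1", call. = FALSE)
  }
  structure(list(
    entropy_threshold = entropy_threshold, entropy_scale = entropy_scale,
    aggregation = aggregation, n_cycles = as.integer(n_cycles),
    loss_pixels_only = isTRUE(loss_pixels_only), seed = as.integer(seed)
  ), class = "lufor_al_config")
}

#' Split an annotated set into training and independent test pools
#'
#' Seeded shuffle, then `floor(train_fraction * n)` ids go to training and
#' the remainder to the test pool. With the reference counts (895 annotated
#' images at 80/20) this yields 716 training and 179 test images.
#'
#' @param n_annotated Number of annotated items (or a vector of ids).
#' @param train_fraction Fraction placed in the training pool, in (0, 1).
#' @param seed Shuffle seed.
#' @return List with integer (or id) vectors `train` and `test`.
#' @export
split_pools <- function(n_annotated, train_fraction = 0.8, seed = 1L) {
  if (train_fraction <= 0 || train_fraction >= 1) {
    stop("train_fraction must lie strictly between 0 and 1", call. = FALSE)
  }
  ids <- if (length(n_annotated) == 1 && is.numeric(n_annotated)) {
    seq_len(n_annotated)
  } else {
    n_annotated
  }
  n <- length(ids)
  if (n < 2) stop("need at least 2 items to split", call. = FALSE)
  n_train <- floor(train_fraction * n)
  withr::with_seed(seed, {
    ord <- sample(n)
    list(train = ids[ord[seq_len(n_train)]], test = ids[ord[(n_train + 1):n]])
  })
}

#' Per-pixel prediction entropy
#'
#' `H(Y) = -sum_i p_i log(p_i)` in nats, with `0 log 0 = 0`. Values lie in
#' `[0, log K]`: 0 for a one-hot pixel, `log K` for a uniform one.
#'
#' @param probs H x W x K probability array (per-pixel simplex).
#' @param tol Simplex tolerance.
#' @return H x W matrix of entropies.
#' @export
pixel_entropy <- function(probs, tol = 1e-5) {
  d <- dim(probs)
  P <- as_prob_matrix(probs)
  if (any(P < -tol) || any(abs(rowSums(P) - 1) > tol)) {
    stop("probabilities are not on the simplex", call. = FALSE)
  }
  H <- -rowSums(ifelse(P > 0, P * log(P), 0)) + 0 # + 0 normalizes IEEE -0
  if (length(d) == 3) matrix(H, d[1], d[2]) else H
}

#' Aggregate a pixel-entropy map into one image uncertainty score
#'
#' @param entropy H x W entropy matrix (nats), e.g. from [pixel_entropy()].
#' @param n_classes K, used for the normalized scale.
#' @param aggregation `"mean"`, `"max"` or `"fraction_above"`.
#' @param entropy_scale `"normalized"` (divide by log K, score in \[0, 1\])
#'   or `"nats"`.
#' @param threshold Pixel-level cutoff used only by `"fraction_above"`.
#' @param mask Optional logical matrix; only masked pixels are aggregated.
#' @return Scalar uncertainty score.
#' @export
image_uncertainty <- function(entropy, n_classes,
                              aggregation = c("mean", "max", "fraction_above"),
                              entropy_scale = c("normalized", "nats"),
                              threshold = 0.6, mask = NULL) {
  aggregation <- match.arg(aggregation)
  entropy_scale <- match.arg(entropy_scale)
  v <- as.vector(entropy)
  if (!is.null(mask)) {
    if (length(mask) != length(v)) stop("mask shape mismatch", call. = FALSE)
    if (any(mask)) v <- v[as.vector(mask)]
  }
  if (entropy_scale == "normalized") v <- v / log(n_classes)
  switch(aggregation,
    mean = mean(v),
    max = max(v),
    fraction_above = mean(v > threshold)
  )
}

# uncertainty scores for a set of scenes under a model
uncertainty_scores <- function(model, pools, ids, config) {
  vapply(ids, function(id) {
    sc <- pools$scenes[[id]]
    probs <- predict_unet(model, build_stack(sc$bands))
    H <- pixel_entropy(probs)
    mask <- if (config$loss_pixels_only) sc$loss_mask else NULL
    image_uncertainty(H, n_classes = model$config$n_classes,
                      aggregation = config$aggregation,
                      entropy_scale = config$entropy_scale,
                      threshold = config$entropy_threshold, mask = mask)
  }, numeric(1))
}

#' Select unannotated images for annotation
#'
#' Scores every unannotated scene with the model and returns exactly those
#' whose uncertainty exceeds the threshold (strict inequality). An empty
#' selection is legal.
#'
#' @param pools A `lufor_pools` object.
#' @param model A trained `lufor_unet`.
#' @param config An [al_config()].
#' @param scores Optional named numeric vector of precomputed uncertainty
#'   scores (names = unannotated scene ids); when supplied the model is not
#'   consulted.
#' @return Tibble with `scene_id` and `uncertainty` of the selected scenes.
#' @export
select_for_annotation <- function(pools, model, config = al_config(), scores = NULL) {
  ids <- pool_ids(pools, "unannotated")
  if (length(ids) == 0) stop("unannotated pool is empty", call. = FALSE)
  sc <- if (is.null(scores)) {
    uncertainty_scores(model, pools, ids, config)
  } else {
    if (!all(ids %in% names(scores))) stop("scores missing for some unannotated scenes", call. = FALSE)
    scores[ids]
  }
  sel <- sc > config$entropy_threshold
  tibble::tibble(scene_id = ids[sel], uncertainty = unname(sc[sel]))
}

#' Reveal clean labels for selected scenes (simulated annotator)
#'
#' Moves the selected scenes from the unannotated to the annotated pool and
#' attaches the generator's clean truth as their labels, emulating a perfect
#' human annotator. Test membership and all other scenes are untouched.
#'
#' @param pools A `lufor_pools` object.
#' @param selected_ids Scene ids, all currently unannotated.
#' @param cycle Cycle index recorded in the manifest.
#' @return The updated `lufor_pools`.
#' @export
simulated_annotator <- function(pools, selected_ids, cycle = 1L) {
  if (length(selected_ids) == 0) return(pools)
  un <- pool_ids(pools, "unannotated")
  bad <- setdiff(selected_ids, un)
  if (length(bad) > 0) {
    stop("not in the unannotated pool: ", paste(bad, collapse = ", "), call. = FALSE)
  }
  sel <- pools$manifest$scene_id %in% selected_ids
  pools$manifest$pool[sel] <- "annotated"
  pools$manifest$cycle_of_annotation[sel] <- as.integer(cycle)
  for (id in selected_ids) {
    pools$labels[[id]] <- pools$scenes[[id]]$truth_mask
  }
  pools
}

# evaluate a model on the clean test pool, pixel-wise
evaluate_on_test <- function(model, pools) {
  ids <- pool_ids(pools, "test")
  k <- model$config$n_classes
  cm <- matrix(0L, k, k)
  for (id in ids) {
    sc <- pools$scenes[[id]]
    probs <- predict_unet(model, build_stack(sc$bands))
    pred <- argmax_map(probs)
    cm <- cm + unclass(confusion(pred, sc$truth_mask, k))
  }
  dimnames(cm) <- list(map = 0:(k - 1), reference = 0:(k - 1))
  class(cm) <- c("lufor_confusion", class(cm))
  cm
}

#' Run the iterative pool-based active-learning loop
#'
#' Trains on the annotated pool, evaluates on the fixed independent test
#' pool, then for each cycle scores the unannotated pool by prediction
#' entropy, sends the above-threshold images to the simulated annotator,
#' and retrains from scratch on the enlarged pool. Produces
#' `n_cycles + 1` reports (initial training plus each round).
#'
#' @param pools A `lufor_pools` dataset.
#' @param mconfig A [model_config()].
#' @param tconfig A [train_config()].
#' @param aconfig An [al_config()].
#' @param loss_params A [focal_params()].
#' @param verbose Print cycle progress.
#' @return List with `reports` (tibble: cycle, n_selected, pool sizes,
#'   macro/micro F1), `per_class` (tibble of per-class F1 by cycle),
#'   `pools` (final state), `model` (final model), `selected` (per-cycle
#'   selection tables). The reports object has class `lufor_al_run`.
#' @export
run_al_loop <- function(pools, mconfig = model_config(n_classes = pools$n_classes),
                        tconfig = train_config(), aconfig = al_config(),
                        loss_params = focal_params(n_classes = pools$n_classes),
                        verbose = FALSE) {
  stopifnot(inherits(pools, "lufor_pools"))
  reports <- list()
  per_class <- list()
  selected <- list()
  model <- NULL
  f <- NULL
  for (cycle in 0:aconfig$n_cycles) {
    grew <- cycle == 0
    if (cycle > 0) {
      if (length(pool_ids(pools, "unannotated")) > 0) {
        sel <- select_for_annotation(pools, model, aconfig)
        selected[[cycle]] <- sel
        pools <- simulated_annotator(pools, sel$scene_id, cycle = cycle)
        grew <- nrow(sel) > 0
      } else {
        selected[[cycle]] <- tibble::tibble(scene_id = character(), uncertainty = numeric())
      }
    }
    if (grew) {
      # retrain from scratch on the enlarged pool; an empty selection adds
      # no information, so the previous model (and its metrics) carry over
      mcfg <- mconfig
      mcfg$seed <- mconfig$seed + cycle # fresh init per retraining round
      tcfg <- tconfig
      tcfg$seed <- tconfig$seed + cycle
      model <- build_unet(mcfg)
      patches <- pools_to_patches(pools, tcfg$patch_size, tcfg$stride)
      train_unet(model, patches, tcfg, loss_params)
      cm <- evaluate_on_test(model, pools)
      f <- f1_scores(cm)
    }
    sizes <- table(factor(pools$manifest$pool, levels = c("annotated", "unannotated", "test")))
    reports[[cycle + 1]] <- tibble::tibble(
      cycle = cycle,
      n_selected = if (cycle == 0) NA_integer_ else nrow(selected[[cycle]]),
      n_annotated = as.integer(sizes[["annotated"]]),
      n_unannotated = as.integer(sizes[["unannotated"]]),
      n_test = as.integer(sizes[["test"]]),
      macro_f1 = f$macro_f1,
      micro_f1 = f$micro_f1
    )
    pc <- f$per_class
    pc$cycle <- cycle
    per_class[[cycle + 1]] <- pc
    if (verbose) {
      message(sprintf("cycle %d: annotated %d, macro F1 %.3f",
                      cycle, sizes[["annotated"]], f$macro_f1))
    }
  }
  out <- list(
    reports = dplyr::bind_rows(reports),
    per_class = dplyr::bind_rows(per_class),
    selected = selected,
    pools = pools,
    model = model
  )
  class(out) <- "lufor_al_run"
  out
}

#' @export
print.lufor_al_run <- function(x, ...) {
  cat("<lufor_al_run>\n")
  print(x$reports)
  invisible(x)
}

#' @export
tidy.lufor_al_run <- function(x, ...) {
  x$per_class
}

#' @export
glance.lufor_al_run <- function(x, ...) {
  r <- x$reports
  tibble::tibble(
    n_cycles = max(r$cycle),
    initial_macro_f1 = r$macro_f1[r$cycle == 0],
    final_macro_f1 = r$macro_f1[r$cycle == max(r$cycle)],
    improvement = r$macro_f1[r$cycle == max(r$cycle)] - r$macro_f1[r$cycle == 0]
  )
}

#' Plot the macro/micro F1 trajectory of an active-learning run
#'
#' @param object A `lufor_al_run`.
#' @param ... Unused.
#' @export
autoplot.lufor_al_run <- function(object, ...) {
  df <- tidyr::pivot_longer(object$reports, c("macro_f1", "micro_f1"),
                            names_to = "metric", values_to = "f1")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cycle, y = .data$f1,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$cycle)) +
    ggplot2::labs(x = "active-learning cycle", y = "F1 on the test pool",
                  colour = NULL) +
    ggplot2::theme_minimal()
}
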