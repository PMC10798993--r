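#' Bundled CPU-scale benchmarks
#'
#' Two fixed experimental setups used by the package's tests and by
#' `scripts/acceptance.R`. Both draw 24 synthetic scenes of 128 x 128 pixels
#' with the 15 default classes, split 8 annotated / 12 unannotated / 4 test.
#'
#' `run_al_benchmark()` reproduces the active-learning experiment: the
#' annotated pool carries corrupted labels (30% mislabeled pixels, 30%
#' dropped labels), the model trains briefly, the unannotated pool is scored
#' by mean normalized prediction entropy over loss pixels, scenes above 0.6
#' are revealed by the simulated annotator, and the cycle repeats. The
#' expected behaviour is a rising macro-F1 trajectory as clean labels enter
#' the pool.
#'
#' `run_clean_benchmark()` is the same dataset with clean, uncorrupted
#' labels and a single (longer) training, measuring what the model recovers
#' when annotations are perfect.
#'
#' Training here is deliberately small (depth 3, 16 base filters, 64 px
#' patches, batch 8, Adam at 3e-3); the methods vignette discusses these
#' choices.
#'
#' @param seed Master seed; per-seed replicates derive their own dataset and
#'   training seeds from it.
#' @param n_seeds Number of independent replicates of the AL experiment.
#' @param n_cycles Active-learning rounds after the initial training.
#' @param epochs Training epochs (per cycle for the AL benchmark).
#' @param verbose Print progress.
#' @return For `run_al_benchmark()`: tibble with one row per (replicate,
#'   cycle) holding pool sizes and macro/micro F1. For
#'   `run_clean_benchmark()`: list with `macro_f1`, `micro_f1`, `per_class`,
#'   `history`, `epochs`.
#' @export
run_al_benchmark <- function(seed = 1L, n_seeds = 3L, n_cycles = 2L,
                             epochs = 14L, verbose = FALSE) {
  out <- list()
  for (s in seq_len(n_seeds)) {
    rep_seed <- derive_seed(seed, "al") + s
    pools <- generate_dataset(
      24L, scene_config(),
      corruption_config(mislabel_fraction = 0.3, drop_fraction = 0.3,
                        seed = rep_seed),
      annotated_fraction = 8 / 24, test_fraction = 4 / 24, seed = rep_seed
    )
    run <- run_al_loop(
      pools,
      mconfig = model_config(seed = rep_seed),
      tconfig = train_config(epochs = epochs, batch_size = 8L,
                             learning_rate = 3e-3, patch_size = 64L,
                             seed = rep_seed),
      aconfig = al_config(n_cycles = n_cycles, seed = rep_seed),
      verbose = verbose
    )
    r <- run$reports
    r$replicate <- s
    out[[s]] <- r
  }
  dplyr::bind_rows(out)
}

#' @rdname run_al_benchmark
#' @export
run_clean_benchmark <- function(seed = 1L, epochs = 50L, verbose = FALSE) {
  bench_seed <- derive_seed(seed, "train") + 1L
  pools <- generate_dataset(
    24L, scene_config(), corruption_config(),
    annotated_fraction = 8 / 24, test_fraction = 4 / 24, seed = bench_seed
  )
  # clean labels: the annotated pool uses the generator's truth
  for (id in pool_ids(pools, "annotated")) {
    pools$labels[[id]] <- pools$scenes[[id]]$truth_mask
  }
  model <- build_unet(model_config(seed = bench_seed))
  tcfg <- train_config(epochs = epochs, batch_size = 8L, learning_rate = 3e-3,
                       patch_size = 64L, seed = bench_seed)
  train_unet(model, pools_to_patches(pools, tcfg$patch_size), tcfg,
             verbose = verbose)
  cm <- evaluate_on_test(model, pools)
  f <- f1_scores(cm)
  list(macro_f1 = f$macro_f1, micro_f1 = f$micro_f1, per_class = f$per_class,
       history = model$history, epochs = epochs)
}
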