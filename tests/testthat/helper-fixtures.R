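# Small shared fixtures, built in code at test time.

# a compact dataset of 32 x 32 scenes for fast structural tests
tiny_pools <- function(n_scenes = 6, seed = 7, mislabel = 0, drop = 0) {
  generate_dataset(
    n_scenes,
    scene_config(height = 32, width = 32),
    corruption_config(mislabel_fraction = mislabel, drop_fraction = drop, seed = seed),
    annotated_fraction = 0.5, test_fraction = 0.2, seed = seed
  )
}

# small untrained model matching the default class count
tiny_model <- function(seed = 0, n_classes = 15) {
  build_unet(model_config(n_classes = n_classes, depth = 2, base_filters = 4,
                          dropout_rate = 0, seed = seed))
}

# a model that emits exactly uniform class probabilities everywhere
uniform_model <- function(n_classes = 15) {
  m <- tiny_model()
  m$params$head_W[] <- 0
  m$params$head_b[] <- 0
  m
}

# random per-pixel simplex array
random_probs <- function(h, w, k, seed = 1) {
  withr::with_seed(seed, {
    p <- array(rexp(h * w * k), dim = c(h, w, k))
    s <- apply(p, c(1, 2), sum)
    p / array(s, dim = c(h, w, k))
  })
}
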