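#' Default pipeline configuration
#'
#' The full analysis behind one nested configuration list: dataset
#' simulation, annotation corruption, model and training settings, focal
#' loss, active learning, stratified assessment and hotspot/trend
#' parameters. The defaults are the package's CPU-scale study conditions;
#' see the methods vignette for the rationale behind each value.
#'
#' @return Nested named list of class `lufor_pipeline_config`.
#' @export
pipeline_config <- function() {
  structure(list(
    seed = 1L,
    output_dir = "lufor_output",
    dataset = list(
      n_scenes = 12L, height = 128L, width = 128L, pixel_size = 5,
      band_sd = 0.02, noise_sd = 0.01, loss_fraction = 0.35,
      n_objects_min = 1L, n_objects_max = 3L,
      annotated_fraction = 0.4, test_fraction = 0.2
    ),
    corruption = list(
      boundary_shift_px = 2L, mislabel_fraction = 0.3,
      drop_fraction = 0.3, polygon_mix_fraction = 0.2
    ),
    model = list(depth = 3L, base_filters = 16L, dropout_rate = 0.1, batch_norm = TRUE),
    train = list(epochs = 15L, batch_size = 8L, learning_rate = 2e-3, patch_size = 64L),
    loss = list(gamma = 2, alpha = 1),
    al = list(entropy_threshold = 0.6, entropy_scale = "normalized",
              aggregation = "mean", n_cycles = 2L),
    assessment = list(n_total = 300L, n_min = 5L, interpreter_error = 0),
    hotspot = list(cell_size = 0.1, bandwidth = 0.1, stride = 4L)
  ), class = "lufor_pipeline_config")
}

# recursive schema check: every key in cfg must exist in the template
check_config_keys <- function(cfg, template, path = "") {
  for (nm in names(cfg)) {
    if (!nm %in% names(template)) {
      stop("unknown configuration key: ", path, nm, call. = FALSE)
    }
    if (is.list(template[[nm]]) && !is.null(names(template[[nm]]))) {
      if (!is.list(cfg[[nm]])) stop("section must be a mapping: ", path, nm, call. = FALSE)
      check_config_keys(cfg[[nm]], template[[nm]], paste0(path, nm, "."))
    }
  }
  invisible(TRUE)
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), validates it against the schema of
#' [pipeline_config()] -- unknown keys are rejected -- and merges it over the
#' defaults.
#'
#' @param config Path to a YAML file, a list of overrides, or NULL for the
#'   defaults.
#' @return A validated `lufor_pipeline_config`.
#' @export
load_config <- function(config = NULL) {
  base <- pipeline_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  if (inherits(config, "lufor_pipeline_config")) return(config)
  check_config_keys(config, base)
  structure(merge_config(unclass(base), config), class = "lufor_pipeline_config")
}

config_objects <- function(cfg) {
  ds <- cfg$dataset
  list(
    scene = scene_config(
      height = ds$height, width = ds$width, pixel_size = ds$pixel_size,
      classes = default_classes(band_sd = ds$band_sd),
      n_objects_per_class = c(ds$n_objects_min, ds$n_objects_max),
      noise_sd = ds$noise_sd, loss_fraction = ds$loss_fraction,
      seed = derive_seed(cfg$seed, "scenes")
    ),
    corruption = corruption_config(
      boundary_shift_px = cfg$corruption$boundary_shift_px,
      mislabel_fraction = cfg$corruption$mislabel_fraction,
      drop_fraction = cfg$corruption$drop_fraction,
      polygon_mix_fraction = cfg$corruption$polygon_mix_fraction,
      seed = derive_seed(cfg$seed, "corrupt")
    ),
    model = model_config(
      n_classes = 15L, depth = cfg$model$depth,
      base_filters = cfg$model$base_filters,
      dropout_rate = cfg$model$dropout_rate,
      batch_norm = cfg$model$batch_norm,
      seed = derive_seed(cfg$seed, "model")
    ),
    train = train_config(
      epochs = cfg$train$epochs, batch_size = cfg$train$batch_size,
      learning_rate = cfg$train$learning_rate,
      patch_size = cfg$train$patch_size,
      seed = derive_seed(cfg$seed, "train")
    ),
    loss = focal_params(n_classes = 15L, alpha = cfg$loss$alpha, gamma = cfg$loss$gamma),
    al = al_config(
      entropy_threshold = cfg$al$entropy_threshold,
      entropy_scale = cfg$al$entropy_scale,
      aggregation = cfg$al$aggregation,
      n_cycles = cfg$al$n_cycles,
      seed = derive_seed(cfg$seed, "al")
    )
  )
}

log_stage <- function(log, stage, t0) {
  msg <- sprintf("[%s] %-10s %.1fs", format(Sys.time(), "%H:%M:%S"), stage,
                 as.numeric(Sys.time()) - t0)
  message(msg)
  if (!is.null(log)) cat(msg, "\n", file = log, append = TRUE)
}

#' Run the full mapping pipeline
#'
#' Orchestrates simulation, active-learning training, masked prediction,
#' per-lustrum stratified assessment, hotspot grids and trend tables behind
#' one configuration, writing every artifact (tagged with the configuration
#' hash) into the output directory:
#' `manifest.csv`, `config_resolved.yaml`, `cycle_reports.csv`,
#' `per_class_f1.csv`, `selected_cycle<k>.csv`, predicted maps and loss
#' masks as TIFF, `assessment_<lustrum>.csv`, `assessment_summary.csv`,
#' `hotspot_class<k>.tif`, `trend.csv`, `country_proportions.csv`, and
#' `log.txt`.
#'
#' @param config Path to a YAML config, an override list, or NULL for
#'   defaults (see [load_config()]).
#' @param stages Character vector of stages, or `"all"`. Stages:
#'   `simulate`, `al_run`, `predict`, `assess`, `hotspots`, `trend`.
#' @param output_dir Overrides the configured output directory.
#' @param seed Overrides the configured global seed.
#' @return Invisible list with the pools, AL run, assessment, hotspot grids
#'   and trend tables produced.
#' @export
run_pipeline <- function(config = NULL, stages = "all", output_dir = NULL, seed = NULL) {
  cfg <- load_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(output_dir)) cfg$output_dir <- output_dir
  all_stages <- c("simulate", "al_run", "predict", "assess", "hotspots", "trend")
  if (identical(stages, "all")) stages <- all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad) > 0) stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  # later stages need the earlier ones in-session
  need <- all_stages[seq_len(max(match(stages, all_stages)))]

  out <- cfg$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  log <- file.path(out, "log.txt")
  hash <- config_hash(unclass(cfg))
  yaml::write_yaml(c(unclass(cfg), list(config_hash = hash)),
                   file.path(out, "config_resolved.yaml"))
  obj <- config_objects(cfg)
  res <- list(config = cfg, hash = hash)

  t0 <- as.numeric(Sys.time())
  pools <- generate_dataset(
    n_scenes = cfg$dataset$n_scenes, config = obj$scene,
    corruption = obj$corruption,
    annotated_fraction = cfg$dataset$annotated_fraction,
    test_fraction = cfg$dataset$test_fraction, seed = cfg$seed
  )
  res$pools <- pools
  if ("simulate" %in% stages) {
    write_manifest(pools, file.path(out, "manifest.csv"))
  }
  log_stage(log, "simulate", t0)

  if (any(c("al_run", "predict", "assess", "hotspots", "trend") %in% need)) {
    t0 <- as.numeric(Sys.time())
    al <- run_al_loop(pools, obj$model, obj$train, obj$al, obj$loss)
    res$al <- al
    write.csv(al$reports, file.path(out, "cycle_reports.csv"), row.names = FALSE)
    write.csv(al$per_class, file.path(out, "per_class_f1.csv"), row.names = FALSE)
    for (i in seq_along(al$selected)) {
      write.csv(al$selected[[i]], file.path(out, sprintf("selected_cycle%d.csv", i)),
                row.names = FALSE)
    }
    log_stage(log, "al_run", t0)
  }

  if (any(c("predict", "assess", "hotspots", "trend") %in% need)) {
    t0 <- as.numeric(Sys.time())
    test_ids <- pool_ids(res$pools, "test")
    preds <- list()
    for (id in test_ids) {
      sc <- res$pools$scenes[[id]]
      probs <- predict_unet(res$al$model, build_stack(sc$bands))
      preds[[id]] <- argmax_map(probs, loss_mask = sc$loss_mask)
      if ("predict" %in% stages) {
        write_mask_tiff(preds[[id]], file.path(out, paste0(id, "_pred.tif")))
      }
    }
    res$predictions <- preds
    log_stage(log, "predict", t0)
  }

  if ("assess" %in% need) {
    t0 <- as.numeric(Sys.time())
    test_ids <- pool_ids(res$pools, "test")
    mos <- function(get) do.call(cbind, lapply(test_ids, get))
    assess <- per_lustrum_assessment(
      class_map = mos(function(id) res$predictions[[id]]),
      loss_year = mos(function(id) res$pools$scenes[[id]]$loss_year),
      reference = mos(function(id) res$pools$scenes[[id]]$truth_mask),
      n_classes = res$pools$n_classes,
      n_total = cfg$assessment$n_total, n_min = cfg$assessment$n_min,
      interpreter_error = cfg$assessment$interpreter_error,
      pixel_area = cfg$dataset$pixel_size^2 / 10000,
      seed = derive_seed(cfg$seed, "assess")
    )
    res$assessment <- assess
    write.csv(assess$summary, file.path(out, "assessment_summary.csv"), row.names = FALSE)
    for (nm in names(assess$estimates)) {
      write.csv(tidy(assess$estimates[[nm]]),
                file.path(out, paste0("assessment_", gsub("-", "_", nm), ".csv")),
                row.names = FALSE)
    }
    log_stage(log, "assess", t0)
  }

  if ("hotspots" %in% need) {
    t0 <- as.numeric(Sys.time())
    test_ids <- pool_ids(res$pools, "test")
    grids <- list()
    for (k in 0:(res$pools$n_classes - 1)) {
      pts <- purrr::map_dfr(test_ids, function(id) {
        class_points(res$predictions[[id]],
                     res$pools$scenes[[id]]$geotransform, k,
                     stride = cfg$hotspot$stride)
      })
      if (nrow(pts) == 0) next
      grids[[as.character(k)]] <- kde_hotspots(
        pts, cell_size = cfg$hotspot$cell_size,
        bandwidth = cfg$hotspot$bandwidth, class_id = k
      )
    }
    res$hotspots <- grids
    if ("hotspots" %in% stages) {
      for (nm in names(grids)) {
        v <- grids[[nm]]$values
        vmax <- max(v)
        tiff::writeTIFF(if (vmax > 0) v / vmax else v,
                        file.path(out, sprintf("hotspot_class%s.tif", nm)))
      }
    }
    log_stage(log, "hotspots", t0)
  }

  if ("trend" %in% need) {
    t0 <- as.numeric(Sys.time())
    test_ids <- pool_ids(res$pools, "test")
    trend <- purrr::map_dfr(test_ids, function(id) {
      sc <- res$pools$scenes[[id]]
      lustrum_region_trend(res$predictions[[id]], sc$loss_year, sc$region_id,
                           sc$pixel_size, n_classes = res$pools$n_classes)
    }) |>
      dplyr::group_by(.data$region_id, .data$class_id, .data$lustrum) |>
      dplyr::summarise(area_ha = sum(.data$area_ha), .groups = "drop_last") |>
      dplyr::group_by(.data$region_id, .data$lustrum) |>
      dplyr::mutate(proportion = .data$area_ha / sum(.data$area_ha)) |>
      dplyr::ungroup()
    res$trend <- trend
    write.csv(trend, file.path(out, "trend.csv"), row.names = FALSE)
    country <- purrr::map_dfr(test_ids, function(id) {
      sc <- res$pools$scenes[[id]]
      cp <- country_proportions(res$predictions[[id]], sc$country_id,
                                n_classes = res$pools$n_classes)
      cp
    }) |>
      dplyr::group_by(.data$country_id, .data$class_id) |>
      dplyr::summarise(percent = mean(.data$percent), .groups = "drop_last") |>
      dplyr::mutate(percent = 100 * .data$percent / sum(.data$percent)) |>
      dplyr::ungroup()
    res$country <- country
    write.csv(country, file.path(out, "country_proportions.csv"), row.names = FALSE)
    log_stage(log, "trend", t0)
  }

  invisible(res)
}
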