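#' Default run configuration
#'
#' All generic settings pre-filled, so an empty override file reproduces the
#' pipeline's canonical behavior: RBF-SVM with C = 1000 and gamma = 0.1, a
#' 1000-feature descriptor budget applied to layers with more than 5000
#' features, 255 histogram bins for the pooling operators, co-occurrence
#' radius 1 with self-channel weight 0, 10 chi-square quantile bins, 5-fold
#' cross-validation, and the batch-30 / LR 3e-4 / 20-epoch / x20-final-layer
#' fine-tuning profile.
#'
#' @return nested configuration list.
#' @export
lf_default_config <- function() {
  list(
    dataset = list(source = "synthetic", path = NULL,
                   n_classes = 3L, per_class = 30L, image_size = 64L,
                   noise_sd = 0.1),
    backbone = list(architecture_id = "tinycnn", seed = 1L, tuned = FALSE),
    recipe = "DCT",
    reducer = list(budget_B = 1000L, threshold_T = 5000L, n_bins_chi = 10L,
                   pooling_bins = 255L, cooc_radius = 1L, cooc_epsilon = 0),
    svm = list(C = 1000, gamma = 0.1),
    cv = list(k = 5L),
    finetune = list(batch_size = 30L, learning_rate = 3e-4, epochs = 20L,
                    final_layer_lr_multiplier = 20),
    sffs = list(target_X = 2L),
    seed = 1L
  )
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    base[[nm]] <- if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      merge_config(base[[nm]], override[[nm]])
    } else override[[nm]]
  }
  base
}

#' Read a run configuration file
#'
#' A YAML file of overrides merged over [lf_default_config()]; an empty or
#' missing file yields the defaults.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return resolved configuration list.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- lf_default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop(sprintf("config file '%s' not found", path))
    ov <- yaml::read_yaml(path)
    if (is.list(ov)) cfg <- merge_config(cfg, ov)
  }
  cfg
}

resolve_run <- function(cfg) {
  if (identical(cfg$dataset$source, "synthetic")) {
    ds <- gen_texture_dataset(texture_dataset_spec(
      n_classes = cfg$dataset$n_classes, per_class = cfg$dataset$per_class,
      image_size = cfg$dataset$image_size, noise_sd = cfg$dataset$noise_sd,
      seed = cfg$seed))
  } else {
    ds <- load_image_dataset(cfg$dataset$path)
  }
  bb <- tiny_backbone(seed = cfg$backbone$seed,
                      n_classes = nlevels(ds$labels),
                      input_size = cfg$dataset$image_size %||% 64L)
  if (isTRUE(cfg$backbone$tuned)) {
    ft <- fine_tune_config(batch_size = cfg$finetune$batch_size,
                           learning_rate = cfg$finetune$learning_rate,
                           epochs = cfg$finetune$epochs,
                           final_layer_lr_multiplier = cfg$finetune$final_layer_lr_multiplier,
                           seed = cfg$seed)
    bb <- fine_tune(bb, ds$images, ds$labels, ft)
  }
  spec <- reducer_spec(budget_B = cfg$reducer$budget_B,
                       threshold_T = cfg$reducer$threshold_T,
                       n_bins_chi = cfg$reducer$n_bins_chi,
                       cooc_radius = cfg$reducer$cooc_radius,
                       cooc_epsilon = cfg$reducer$cooc_epsilon)
  list(cfg = cfg, dataset = ds, backbone = bb, spec = spec)
}

write_manifest <- function(cfg, out_dir, extra = list()) {
  man <- c(list(config = cfg, created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                package_version = as.character(utils::packageVersion("layerfuse"))),
           extra)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(man)
}

log_msg <- function(...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(...)))
}
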