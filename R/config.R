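# Hierarchical run configuration: one YAML file with per-module blocks,
# dot-path overrides, and byte-stable round-tripping.

#' Default run configuration
#'
#' One hierarchical list with `phantom`, `network`, `augmentation` and
#' `training` blocks mirroring [phantom_spec()], [network_config()],
#' [augmentation_spec()] and [train_config()].
#'
#' @return Nested named list.
#' @export
default_config <- function() {
  list(
    phantom = list(grid_size = 128, n_blobs = 3, contrast = 0.3,
                   noise_sd = 0.2, blur_sigma = 1.5, bias_amplitude = 0.2,
                   seed = 1, n = 20),
    preprocess = list(target_shape = c(128, 128), center = "auto"),
    network = list(input_size = 128, base_width = 64, n_down_stages = 4,
                   classifier = "sigmoid_1ch", stem_branch_width = 16,
                   stem_pool_stride = 1),
    augmentation = list(enabled = FALSE,
                        methods = c("vertical_flip", "horizontal_flip",
                                    "random_rotation", "random_translation",
                                    "elastic_deformation"),
                        rotation_range = 15, translation_range = 0.1,
                        elastic_alpha = 10, elastic_sigma = 4, seed = 1),
    training = list(learning_rate = 0.001, batch_size = 8,
                    l2_weight = 1e-4, epochs = 50, seed = 1, split = 0.8,
                    threshold = 0.5, optimizer = "adam"))
}

#' Read a YAML run configuration, filling defaults
#' @param path YAML file path, or `NULL` for the defaults.
#' @return Nested named list.
#' @export
read_config <- function(path = NULL) {
  cfg <- default_config()
  if (is.null(path)) return(cfg)
  user <- yaml::read_yaml(path)
  modifyList(cfg, user)
}

#' Write a run configuration as YAML
#' @param cfg Nested named list.
#' @param path Destination path.
#' @export
write_config <- function(cfg, path) {
  writeLines(yaml::as.yaml(cfg), path)
  invisible(path)
}

#' Apply `key.path=value` overrides to a configuration
#' @param cfg Nested named list.
#' @param overrides Character vector like `"training.epochs=3"`.
#' @return The updated configuration.
#' @export
apply_overrides <- function(cfg, overrides) {
  for (ov in overrides) {
    kv <- strsplit(ov, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      ms_stop("msunet_config_error", paste("bad override:", ov))
    keys <- strsplit(kv[1], ".", fixed = TRUE)[[1]]
    val <- utils::type.convert(kv[2], as.is = TRUE)
    cfg <- set_path(cfg, keys, val)
  }
  cfg
}

set_path <- function(x, keys, val) {
  if (length(keys) == 1) {
    x[[keys]] <- val
    return(x)
  }
  x[[keys[1]]] <- set_path(if (is.null(x[[keys[1]]])) list()
                           else x[[keys[1]]], keys[-1], val)
  x
}

config_network <- function(cfg) {
  n <- cfg$network
  network_config(input_size = n$input_size, base_width = n$base_width,
                 n_down_stages = n$n_down_stages, classifier = n$classifier,
                 stem_branch_width = n$stem_branch_width,
                 stem_pool_stride = n$stem_pool_stride)
}

config_phantom <- function(cfg) {
  p <- cfg$phantom
  phantom_spec(grid_size = p$grid_size, n_blobs = p$n_blobs,
               contrast = p$contrast, noise_sd = p$noise_sd,
               blur_sigma = p$blur_sigma, bias_amplitude = p$bias_amplitude,
               seed = p$seed)
}

config_training <- function(cfg) {
  t <- cfg$training
  aug <- NULL
  if (isTRUE(cfg$augmentation$enabled)) {
    a <- cfg$augmentation
    aug <- augmentation_spec(methods = a$methods,
                             rotation_range = a$rotation_range,
                             translation_range = a$translation_range,
                             elastic_alpha = a$elastic_alpha,
                             elastic_sigma = a$elastic_sigma, seed = a$seed)
  }
  train_config(learning_rate = t$learning_rate, batch_size = t$batch_size,
               l2_weight = t$l2_weight, epochs = t$epochs, seed = t$seed,
               split = t$split, augmentation = aug, threshold = t$threshold,
               optimizer = t$optimizer)
}
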