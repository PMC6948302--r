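#' Configure the segmentation network
#'
#' The full architectural plan: a multiscale stem feeding a channel-doubling
#' U-net whose contracting path halves the spatial size `n_down_stages`
#' times via stride-2 2x2 down-convolutions (128 -> 8 under the defaults)
#' while channels grow `base_width -> base_width * 2^n_down_stages`
#' (64 -> 1024), an expanding path of `n_down_stages - 1` deconvolution
#' blocks with skip cascades, and a decoder head performing the final
#' upsample back to the input resolution before a 1x1 classifier.
#'
#' @param input_size Input side length in pixels; must be divisible by
#'   `2^n_down_stages` (default 128).
#' @param base_width Channels of the first U-net convolution block
#'   (default 64). The stem's trailing width is `base_width / 2` so the
#'   first block's channel doubling lands exactly on `base_width`.
#' @param n_down_stages Number of spatial halvings (default 4).
#' @param n_unet_up_blocks Deconvolution blocks inside the U-net; must equal
#'   `n_down_stages - 1` (the final upsample lives in the decoder head).
#' @param classifier `"sigmoid_1ch"` (default) or `"softmax_2ch"` (two
#'   logits whose softmax foreground probability is returned; equivalent to
#'   a sigmoid over the logit difference).
#' @param stem_branch_width Channels per stem branch (default 16).
#' @param stem_pool_stride Stride of the stem max-pool (default 1,
#'   size-preserving).
#' @return An object of class `ms_network_config`.
#' @export
network_config <- function(input_size = 128, base_width = 64,
                           n_down_stages = 4,
                           n_unet_up_blocks = n_down_stages - 1,
                           classifier = c("sigmoid_1ch", "softmax_2ch"),
                           stem_branch_width = 16, stem_pool_stride = 1) {
  classifier <- match.arg(classifier)
  if (input_size %% 2^n_down_stages != 0)
    ms_stop("msunet_config_error",
            "input_size must be divisible by 2^n_down_stages")
  if (n_unet_up_blocks + 1 != n_down_stages)
    ms_stop("msunet_config_error",
            "n_unet_up_blocks + 1 must equal n_down_stages")
  if (base_width %% 2 != 0)
    ms_stop("msunet_config_error", "base_width must be even")
  structure(list(input_size = as.integer(input_size),
                 base_width = as.integer(base_width),
                 n_down_stages = as.integer(n_down_stages),
                 n_unet_up_blocks = as.integer(n_unet_up_blocks),
                 classifier = classifier,
                 stem_branch_width = as.integer(stem_branch_width),
                 stem_pool_stride = as.integer(stem_pool_stride)),
            class = "ms_network_config")
}

#' Instantiate the network
#'
#' Allocates all layers with glorot-normal weights under the given seed.
#'
#' @param cfg A [network_config()].
#' @param seed Initialization seed.
#' @return An object of class `ms_model`.
#' @export
build_network <- function(cfg = network_config(), seed = 1) {
  stopifnot(inherits(cfg, "ms_network_config"))
  with_seed(seed, {
    nd <- cfg$n_down_stages
    widths <- cfg$base_width * 2^(0:nd)           # e.g. 64 128 256 512 1024
    stem <- build_stem(cfg$stem_branch_width, cfg$base_width / 2,
                       cfg$stem_pool_stride)
    down_blocks <- vector("list", nd)
    down_convs <- vector("list", nd)
    in_ch <- cfg$base_width / 2
    for (s in seq_len(nd)) {
      down_blocks[[s]] <- build_conv_block(in_ch, widths[s])
      down_convs[[s]] <- build_down_conv(widths[s])
      in_ch <- widths[s]
    }
    bottleneck <- build_conv_block(widths[nd], widths[nd + 1])
    up_blocks <- vector("list", cfg$n_unet_up_blocks)
    ch <- widths[nd + 1]
    for (u in seq_len(cfg$n_unet_up_blocks)) {
      up_blocks[[u]] <- build_deconv_block(ch, ch / 2, ch / 2)
      ch <- ch / 2
    }
    head <- build_decoder_head(ch)
    n_logits <- if (cfg$classifier == "sigmoid_1ch") 1L else 2L
    classifier <- new_sequential(list(
      layer_conv(ch / 2, n_logits, c(1, 1), pad = 0)))
    structure(list(cfg = cfg, stem = stem, down_blocks = down_blocks,
                   down_convs = down_convs, bottleneck = bottleneck,
                   up_blocks = up_blocks, head = head,
                   classifier = classifier),
              class = "ms_model")
  })
}

model_blocks <- function(model) {
  c(list(model$stem), model$down_blocks, model$down_convs,
    list(model$bottleneck), model$up_blocks,
    list(model$head, model$classifier))
}

model_layers <- function(model) {
  collect <- function(b) {
    if (inherits(b, "ms_sequential")) b$layers
    else if (inherits(b, "ms_stem"))
      c(unlist(lapply(b$branches, collect), use.names = FALSE),
        collect(b$post))
    else if (inherits(b, "ms_deconv_block")) c(collect(b$up), collect(b$post))
    else list(b)
  }
  unlist(lapply(model_blocks(model), collect), use.names = FALSE)
}

# logits -> foreground probability map [H, W, 1]
classifier_prob <- function(model, logits, training) {
  if (model$cfg$classifier == "sigmoid_1ch") {
    p <- 1 / (1 + exp(-logits))
    list(prob = p, cache = if (training) list(y = p))
  } else {
    # softmax over 2 channels == sigmoid of the logit difference
    z <- logits[, , 1, drop = FALSE] - logits[, , 2, drop = FALSE]
    p <- 1 / (1 + exp(-z))
    list(prob = p, cache = if (training) list(p = p))
  }
}

forward_network <- function(model, x, training = FALSE) {
  x <- as_chw(x)
  if (!all(dim(x)[1:2] == model$cfg$input_size))
    ms_stop("msunet_geometry_error",
            "input spatial size does not match the network configuration")
  caches <- list()
  sr <- forward_stem(model$stem, x, training)
  caches$stem <- sr$caches
  h <- sr$out
  skips <- list()
  caches$down <- list()
  for (s in seq_along(model$down_blocks)) {
    br <- forward_seq(model$down_blocks[[s]], h, training)
    skips[[s]] <- br$out
    dr <- forward_seq(model$down_convs[[s]], br$out, training)
    h <- dr$out
    caches$down[[s]] <- list(block = br$caches, down = dr$caches)
  }
  bo <- forward_seq(model$bottleneck, h, training)
  caches$bottleneck <- bo$caches
  h <- bo$out
  caches$up <- list()
  nu <- length(model$up_blocks)
  for (u in seq_len(nu)) {
    skip <- skips[[length(skips) - u + 1]]
    ur <- forward_deconv_block(model$up_blocks[[u]], h, skip, training)
    h <- ur$out
    caches$up[[u]] <- ur$caches
  }
  hr <- forward_seq(model$head, h, training)
  caches$head <- hr$caches
  cr <- forward_seq(model$classifier, hr$out, training)
  caches$classifier <- cr$caches
  pr <- classifier_prob(model, cr$out, training)
  caches$prob <- pr$cache
  list(prob = pr$prob, caches = caches)
}

backward_network <- function(model, caches, dprob) {
  dprob <- as_chw(dprob)
  if (model$cfg$classifier == "sigmoid_1ch") {
    p <- caches$prob$y
    dlogits <- dprob * p * (1 - p)
  } else {
    p <- caches$prob$p
    dz <- dprob * p * (1 - p)
    dlogits <- concat_channels(dz, -dz)
  }
  dh <- backward_seq(model$classifier, caches$classifier, dlogits)
  dh <- backward_seq(model$head, caches$head, dh)
  nu <- length(model$up_blocks)
  dskips <- vector("list", length(model$down_blocks))
  for (u in rev(seq_len(nu))) {
    r <- backward_deconv_block(model$up_blocks[[u]], caches$up[[u]], dh)
    dh <- r$dx
    dskips[[length(dskips) - u + 1]] <- r$dskip
  }
  dh <- backward_seq(model$bottleneck, caches$bottleneck, dh)
  for (s in rev(seq_along(model$down_blocks))) {
    dblk <- backward_seq(model$down_convs[[s]], caches$down[[s]]$down, dh)
    if (!is.null(dskips[[s]])) dblk <- dblk + dskips[[s]]
    dh <- backward_seq(model$down_blocks[[s]], caches$down[[s]]$block, dblk)
  }
  backward_stem(model$stem, caches$stem, dh)
}

#' Run the network on a normalized image
#'
#' Evaluation-mode forward pass (batch-norm uses running statistics, so
#' repeated calls are bit-identical).
#'
#' @param model An [build_network()] model.
#' @param image Normalized image matrix matching the configured input size.
#' @return Probability map (matrix in `[0, 1]`, same spatial shape).
#' @export
predict_prob <- function(model, image) {
  stopifnot(inherits(model, "ms_model"))
  r <- forward_network(model, image, training = FALSE)
  matrix(r$prob, dim(r$prob)[1], dim(r$prob)[2])
}

#' Threshold a probability map into a binary mask
#'
#' @param prob Probability map with values in `[0, 1]`.
#' @param threshold Decision threshold in `(0, 1)`; a pixel is foreground
#'   iff its probability is `>= threshold`.
#' @return Integer binary mask, same shape.
#' @export
predict_mask <- function(prob, threshold = 0.5) {
  if (threshold <= 0 || threshold >= 1)
    ms_stop("msunet_config_error", "threshold must be in (0, 1)")
  m <- (prob >= threshold) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Static shape and channel audit of a network configuration
#'
#' Predicts every stage's output resolution and channel count from the
#' size formula alone (no weights are allocated), returning the
#' contraction/expansion table: 128 -> 8 spatial, 64 -> 1024 channels under
#' the defaults.
#'
#' @param cfg A [network_config()].
#' @return A data frame with columns `stage`, `size`, `channels`.
#' @export
audit_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "ms_network_config"))
  nd <- cfg$n_down_stages
  widths <- as.integer(cfg$base_width * 2^(0:nd))
  size <- cfg$input_size
  rows <- list(list(stage = "input", size = size, channels = 1L))
  stem_pool_out <- if (cfg$stem_pool_stride == 1) size else size %/% 2L
  rows <- c(rows, list(list(stage = "stem", size = stem_pool_out,
                            channels = cfg$base_width %/% 2L)))
  size <- stem_pool_out
  for (s in seq_len(nd)) {
    size_block <- conv_output_size(size, kernel = 3, stride = 1, padding = 1)
    rows <- c(rows, list(list(stage = sprintf("conv_block_%d", s),
                              size = size_block, channels = widths[s])))
    size <- conv_output_size(size_block, kernel = 2, stride = 2, padding = 0)
    rows <- c(rows, list(list(stage = sprintf("down_conv_%d", s),
                              size = size, channels = widths[s])))
  }
  rows <- c(rows, list(list(stage = "bottleneck", size = size,
                            channels = widths[nd + 1])))
  ch <- widths[nd + 1]
  for (u in seq_len(cfg$n_unet_up_blocks)) {
    size <- size * 2L
    ch <- ch %/% 2L
    rows <- c(rows, list(list(stage = sprintf("deconv_block_%d", u),
                              size = size, channels = ch)))
  }
  size <- size * 2L
  rows <- c(rows, list(list(stage = "decoder_head", size = size,
                            channels = ch %/% 2L)))
  rows <- c(rows, list(list(stage = "classifier", size = size,
                            channels = 1L)))
  do.call(rbind, lapply(rows, as.data.frame))
}

# ---- checkpointing ----------------------------------------------------------

#' Extract all trainable parameters and BN statistics as a flat list
#' @param model An `ms_model`.
#' @return Named list of numeric arrays.
#' @export
collect_params <- function(model) {
  layers <- model_layers(model)
  out <- list()
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in c(layer_param_names(l),
                if (l$type == "bn") c("run_mean", "run_var")))
      out[[sprintf("L%03d_%s", i, p)]] <- get(p, envir = l)
  }
  out
}

#' Load parameters produced by [collect_params()] back into a model
#' @param model An `ms_model` with the same architecture.
#' @param params Named list from [collect_params()].
#' @return The model, invisibly (layers are mutated in place).
#' @export
set_params <- function(model, params) {
  layers <- model_layers(model)
  for (i in seq_along(layers)) {
    l <- layers[[i]]
    for (p in c(layer_param_names(l),
                if (l$type == "bn") c("run_mean", "run_var"))) {
      key <- sprintf("L%03d_%s", i, p)
      if (is.null(params[[key]]))
        ms_stop("msunet_config_error",
                paste("checkpoint is missing parameter", key))
      assign(p, params[[key]], envir = l)
    }
  }
  invisible(model)
}

#' Save a model checkpoint (weights + configuration) to an RDS file
#' @param model An `ms_model`.
#' @param path Output file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(cfg = model$cfg, params = collect_params(model)), path)
}

#' Load a model checkpoint written by [save_checkpoint()]
#' @param path Checkpoint file path.
#' @return A reconstructed `ms_model`.
#' @export
load_checkpoint <- function(path) {
  ck <- readRDS(path)
  model <- build_network(ck$cfg, seed = 1)
  set_params(model, ck$params)
  model
}
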