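#' Describe a convolution layer plan
#'
#' A declarative description of one convolution layer, used by the shape,
#' receptive-field and parameter auditors and by the block builders.
#'
#' @param kernel Kernel extent, scalar or `c(h, w)` (asymmetric kernels such
#'   as 1x3 / 3x1 factorized pairs are allowed).
#' @param stride Stride (>= 1).
#' @param padding Zero padding per side, scalar or `c(h, w)`; `NULL` means
#'   size-preserving ("same") padding for the given dilation.
#' @param dilation Dilation rate (>= 1); taps are spaced `dilation` pixels
#'   apart, so the effective kernel extent is `dilation * (kernel - 1) + 1`.
#' @param in_channels,out_channels Channel counts (needed for parameter
#'   counting; may be `NA` for pure geometry audits).
#' @param has_bn Whether a batch-normalization layer follows.
#' @param activation One of `"relu"`, `"sigmoid"`, `"none"`.
#' @return An object of class `ms_conv_plan`.
#' @export
conv_plan <- function(kernel = 3, stride = 1, padding = NULL, dilation = 1,
                      in_channels = NA, out_channels = NA, has_bn = TRUE,
                      activation = "relu") {
  kernel <- rep(as.integer(kernel), length.out = 2)
  if (any(kernel < 1) || stride < 1 || dilation < 1)
    ms_stop("msunet_config_error",
            "kernel, stride and dilation must all be >= 1")
  if (is.null(padding)) padding <- dilation * (kernel - 1L) %/% 2L
  padding <- rep(as.integer(padding), length.out = 2)
  if (any(padding < 0))
    ms_stop("msunet_config_error", "padding must be >= 0")
  structure(list(kernel = kernel, stride = as.integer(stride),
                 padding = padding, dilation = as.integer(dilation),
                 in_channels = in_channels, out_channels = out_channels,
                 has_bn = has_bn, activation = activation),
            class = "ms_conv_plan")
}

#' Output size of a convolution (zero-padded size formula)
#'
#' Evaluates `floor((I - F_eff + 2P) / S) + 1` per axis, where
#' `F_eff = d * (F - 1) + 1` is the dilated kernel extent. With F = 3, P = 1,
#' S = 1 this preserves the input size, which is how the network keeps
#' 128 x 128 feature maps through every in-block convolution.
#'
#' @param input_size Input extent in pixels (scalar or per-axis).
#' @param plan An [conv_plan()], or `NULL` to pass geometry directly.
#' @param kernel,stride,padding,dilation Geometry when `plan` is `NULL`.
#' @return Output extent (integer, same length as `input_size`).
#' @export
conv_output_size <- function(input_size, plan = NULL, kernel = 3, stride = 1,
                             padding = 1, dilation = 1) {
  if (!is.null(plan)) {
    stopifnot(inherits(plan, "ms_conv_plan"))
    kernel <- plan$kernel; stride <- plan$stride
    padding <- plan$padding; dilation <- plan$dilation
  }
  kernel <- rep(kernel, length.out = length(input_size))
  padding <- rep(padding, length.out = length(input_size))
  f_eff <- dilation * (kernel - 1) + 1
  out <- (input_size - f_eff + 2 * padding) %/% stride + 1L
  if (any(out < 1))
    ms_stop("msunet_geometry_error",
            "convolution output size would be nonpositive")
  as.integer(out)
}

#' Cumulative receptive field of a stride-1 convolution stack
#'
#' Starting from `RF = 1`, each layer adds `(F - 1) * d` pixels of support:
#' a single 3x3 convolution sees 3 pixels, adding a dilation-2 layer grows
#' the field to 7, and a further dilation-4 layer to 15 — the multiscale
#' progression the encoder stem's dilated branches are built around.
#'
#' @param plans Non-empty list of [conv_plan()]s, all with stride 1,
#'   evaluated left to right.
#' @return Receptive-field side length in pixels (scalar when square, else
#'   `c(h, w)`).
#' @export
stacked_receptive_field <- function(plans) {
  if (inherits(plans, "ms_conv_plan")) plans <- list(plans)
  if (length(plans) == 0)
    ms_stop("msunet_config_error", "plan list is empty")
  rf <- c(1L, 1L)
  for (p in plans) {
    stopifnot(inherits(p, "ms_conv_plan"))
    if (p$stride != 1)
      ms_stop("msunet_config_error",
              "receptive-field recurrence requires stride 1 throughout")
    rf <- rf + (p$kernel - 1L) * p$dilation
  }
  if (rf[1] == rf[2]) rf[1] else rf
}

#' Count trainable parameters of a plan, layer or composite block
#'
#' Counts weights + biases for (transposed) convolutions and 2 x channels for
#' each batch-normalization layer. For instantiated layers the count is taken
#' from the allocated arrays, so plan arithmetic can be cross-checked against
#' the engine's actual trainable parameters.
#'
#' @param x A [conv_plan()], an instantiated layer, or a composite block.
#' @return Integer parameter count.
#' @export
count_parameters <- function(x) {
  if (inherits(x, "ms_conv_plan")) {
    if (is.na(x$in_channels) || is.na(x$out_channels))
      ms_stop("msunet_config_error",
              "parameter counting needs channel counts")
    n <- prod(x$kernel) * x$in_channels * x$out_channels + x$out_channels
    if (isTRUE(x$has_bn)) n <- n + 2 * x$out_channels
    return(as.integer(n))
  }
  if (inherits(x, "ms_layer")) {
    return(as.integer(sum(vapply(layer_param_names(x),
                                 function(p) length(get(p, envir = x)), 0))))
  }
  if (inherits(x, "ms_sequential"))
    return(sum(vapply(x$layers, count_parameters, 0L)))
  if (inherits(x, "ms_stem"))
    return(sum(vapply(x$branches, count_parameters, 0L)) +
             count_parameters(x$post))
  if (inherits(x, "ms_deconv_block"))
    return(count_parameters(x$up) + count_parameters(x$post))
  if (inherits(x, "ms_model"))
    return(sum(vapply(model_blocks(x), count_parameters, 0L)))
  ms_stop("msunet_config_error", "cannot count parameters of this object")
}

# ---- composite blocks -------------------------------------------------------

new_sequential <- function(layers) {
  structure(list(layers = layers), class = "ms_sequential")
}

forward_seq <- function(block, x, training = FALSE) {
  caches <- vector("list", length(block$layers))
  for (i in seq_along(block$layers)) {
    r <- layer_forward(block$layers[[i]], x, training)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

backward_seq <- function(block, caches, dy) {
  for (i in rev(seq_along(block$layers)))
    dy <- layer_backward(block$layers[[i]], caches[[i]], dy)
  dy
}

conv_bn_relu <- function(in_ch, out_ch, kernel = c(3, 3), stride = 1,
                         pad = NULL, dilation = 1) {
  list(layer_conv(in_ch, out_ch, kernel, stride, pad, dilation),
       layer_bn(out_ch), layer_relu())
}

#' Build the multiscale encoder stem
#'
#' Five parallel branches over the 1-channel input — a 1x1 convolution, a
#' factorized 3x3 (1x3 then 3x1), a factorized 5x5 (1x5 then 5x1), a 3x3
#' dilation-2 convolution and a 3x3 dilation-4 convolution — each of
#' `branch_width` channels with BN + ReLU, zero-padded so all branches keep
#' the input's spatial size and concatenate to `5 * branch_width` channels.
#' Two trailing 3x3 convolutions map the concatenation to `post_conv_width`
#' channels, followed by a 2x2 max-pool (stride 1, size-preserving, by
#' default; set `pool_stride = 2` to put the pool on the halving path).
#'
#' @param branch_width Channels per parallel branch (default 16).
#' @param post_conv_width Channels of the two trailing 3x3 convolutions.
#' @param pool_stride Stride of the final max-pool (1 preserves size).
#' @return A composite block of class `ms_stem`.
#' @export
build_stem <- function(branch_width = 16, post_conv_width = 32,
                       pool_stride = 1) {
  bw <- branch_width
  branches <- list(
    b1x1 = new_sequential(conv_bn_relu(1, bw, c(1, 1), pad = 0)),
    b3x3 = new_sequential(c(conv_bn_relu(1, bw, c(1, 3), pad = c(0, 1)),
                            conv_bn_relu(bw, bw, c(3, 1), pad = c(1, 0)))),
    b5x5 = new_sequential(c(conv_bn_relu(1, bw, c(1, 5), pad = c(0, 2)),
                            conv_bn_relu(bw, bw, c(5, 1), pad = c(2, 0)))),
    bd2 = new_sequential(conv_bn_relu(1, bw, c(3, 3), pad = 2, dilation = 2)),
    bd4 = new_sequential(conv_bn_relu(1, bw, c(3, 3), pad = 4, dilation = 4)))
  post <- new_sequential(c(conv_bn_relu(5 * bw, post_conv_width),
                           conv_bn_relu(post_conv_width, post_conv_width),
                           list(layer_maxpool(2, pool_stride))))
  structure(list(branches = branches, post = post,
                 branch_width = bw, post_conv_width = post_conv_width),
            class = "ms_stem")
}

forward_stem <- function(stem, x, training = FALSE) {
  x <- as_chw(x)
  rs <- lapply(stem$branches, forward_seq, x = x, training = training)
  cat_in <- do.call(concat_channels, lapply(rs, `[[`, "out"))
  pr <- forward_seq(stem$post, cat_in, training)
  list(out = pr$out,
       caches = list(branches = lapply(rs, `[[`, "caches"),
                     post = pr$caches))
}

backward_stem <- function(stem, caches, dy) {
  dcat <- backward_seq(stem$post, caches$post, dy)
  dx <- NULL
  ch0 <- 0L
  for (nm in names(stem$branches)) {
    bw <- stem$branch_width
    dpart <- dcat[, , (ch0 + 1):(ch0 + bw), drop = FALSE]
    dxi <- backward_seq(stem$branches[[nm]], caches$branches[[nm]], dpart)
    dx <- if (is.null(dx)) dxi else dx + dxi
    ch0 <- ch0 + bw
  }
  dx
}

#' Build a contracting-path convolution block
#'
#' Two zero-padded 3x3 stride-1 convolutions with BN + ReLU; the first
#' doubles the channel count (`in_ch` to `out_ch`).
#'
#' @param in_ch,out_ch Input/output channels.
#' @return A composite block of class `ms_sequential`.
#' @export
build_conv_block <- function(in_ch, out_ch) {
  new_sequential(c(conv_bn_relu(in_ch, out_ch), conv_bn_relu(out_ch, out_ch)))
}

# stride-2 2x2 down-convolution (halves the spatial size, keeps channels)
build_down_conv <- function(ch) {
  new_sequential(conv_bn_relu(ch, ch, c(2, 2), stride = 2, pad = 0))
}

#' Build an expanding-path deconvolution block
#'
#' A stride-2 3x3 transposed convolution doubles the spatial size and halves
#' the channels; the result is cascaded (channel-concatenated) with the
#' matching-resolution skip features, then two 3x3 convolutions reduce back
#' to `out_ch`, all with BN + ReLU.
#'
#' @param in_ch Input channels (e.g. 1024 at the bottleneck).
#' @param skip_ch Channels of the skip features (must equal `in_ch / 2`).
#' @param out_ch Output channels (equal to `in_ch / 2`).
#' @return A composite block of class `ms_deconv_block`.
#' @export
build_deconv_block <- function(in_ch, skip_ch, out_ch) {
  if (skip_ch != in_ch / 2 || out_ch != in_ch / 2)
    ms_stop("msunet_config_error",
            "deconv block expects skip_ch = out_ch = in_ch / 2")
  up <- new_sequential(c(list(layer_tconv(in_ch, in_ch / 2)),
                         list(layer_bn(in_ch / 2), layer_relu())))
  post <- new_sequential(c(conv_bn_relu(in_ch / 2 + skip_ch, out_ch),
                           conv_bn_relu(out_ch, out_ch)))
  structure(list(up = up, post = post, skip_ch = skip_ch),
            class = "ms_deconv_block")
}

forward_deconv_block <- function(block, x, skip, training = FALSE) {
  ur <- forward_seq(block$up, x, training)
  cat_in <- concat_channels(ur$out, skip)
  pr <- forward_seq(block$post, cat_in, training)
  list(out = pr$out, caches = list(up = ur$caches, post = pr$caches,
                                   up_ch = dim(ur$out)[3]))
}

backward_deconv_block <- function(block, caches, dy) {
  dcat <- backward_seq(block$post, caches$post, dy)
  uc <- caches$up_ch
  dup <- dcat[, , 1:uc, drop = FALSE]
  dskip <- dcat[, , (uc + 1):dim(dcat)[3], drop = FALSE]
  dx <- backward_seq(block$up, caches$up, dup)
  list(dx = dx, dskip = dskip)
}

#' Build the decoder head
#'
#' One stride-2 3x3 transposed convolution (restoring the input resolution
#' and halving the channels) followed by one 3x3 convolution, each with
#' BN + ReLU. The classifier (1x1 convolution + sigmoid) is attached by the
#' network assembler.
#'
#' @param in_ch Input channels.
#' @return A composite block of class `ms_sequential`.
#' @export
build_decoder_head <- function(in_ch) {
  new_sequential(c(list(layer_tconv(in_ch, in_ch / 2),
                        layer_bn(in_ch / 2), layer_relu()),
                   conv_bn_relu(in_ch / 2, in_ch / 2)))
}

#' Empirically measure the receptive field of a convolution stack
#'
#' Instantiates the stack with strictly positive weights and zero biases,
#' backpropagates a unit impulse from the centre output pixel, and measures
#' the support width of the nonzero input gradient. This is the brute-force
#' cross-check for [stacked_receptive_field()].
#'
#' @param plans List of [conv_plan()]s (stride 1).
#' @param input_size Probe image side length; must exceed the expected field.
#' @return Measured support side length in pixels, `c(h, w)` collapsed to a
#'   scalar when square.
#' @export
measure_receptive_field <- function(plans, input_size = 64) {
  if (inherits(plans, "ms_conv_plan")) plans <- list(plans)
  layers <- lapply(plans, function(p) {
    l <- layer_conv(1, 1, p$kernel, p$stride, p$padding, p$dilation)
    l$W <- abs(l$W) + 0.1   # no cancellation
    l
  })
  blk <- new_sequential(layers)
  x <- array(0, dim = c(input_size, input_size, 1))
  fr <- forward_seq(blk, x, training = TRUE)
  dy <- array(0, dim = dim(fr$out))
  ctr <- ceiling(dim(fr$out)[1:2] / 2)
  dy[ctr[1], ctr[2], 1] <- 1
  dx <- backward_seq(blk, fr$caches, dy)
  nz <- which(abs(dx[, , 1]) > 1e-12, arr.ind = TRUE)
  rf <- c(diff(range(nz[, 1])) + 1L, diff(range(nz[, 2])) + 1L)
  if (rf[1] == rf[2]) rf[1] else rf
}
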