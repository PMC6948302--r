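# Layer engine. Each layer is a mutable environment holding parameters,
# gradient accumulators and (for BN) running statistics. Tensors are [H, W, C]
# arrays; a matrix is promoted to a single-channel array. Convolution and
# transposed convolution run through the C++ im2col/GEMM kernels.

glorot_normal <- function(n, fan_in, fan_out) {
  rnorm(n, 0, sqrt(2 / (fan_in + fan_out)))
}

new_layer <- function(type, ...) {
  e <- new.env(parent = emptyenv())
  e$type <- type
  fields <- list(...)
  for (nm in names(fields)) assign(nm, fields[[nm]], envir = e)
  class(e) <- c(paste0("ms_layer_", type), "ms_layer")
  e
}

layer_conv <- function(in_ch, out_ch, kernel = c(3, 3), stride = 1,
                       pad = NULL, dilation = 1) {
  kernel <- rep(as.integer(kernel), length.out = 2)
  if (is.null(pad)) pad <- dilation * (kernel - 1) %/% 2  # "same" for odd k
  pad <- rep(as.integer(pad), length.out = 2)
  k <- prod(kernel)
  W <- matrix(glorot_normal(k * in_ch * out_ch, k * in_ch, k * out_ch),
              k * in_ch, out_ch)
  new_layer("conv", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
            stride = as.integer(stride), pad = pad,
            dilation = as.integer(dilation),
            W = W, b = numeric(out_ch), gW = NULL, gb = NULL)
}

layer_tconv <- function(in_ch, out_ch, kernel = c(3, 3), stride = 2,
                        pad = 1) {
  kernel <- rep(as.integer(kernel), length.out = 2)
  k <- prod(kernel)
  W <- matrix(glorot_normal(k * out_ch * in_ch, k * in_ch, k * out_ch),
              k * out_ch, in_ch)
  new_layer("tconv", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
            stride = as.integer(stride), pad = as.integer(pad),
            W = W, b = numeric(out_ch), gW = NULL, gb = NULL)
}

layer_bn <- function(ch, momentum = 0.99, eps = 1e-5) {
  new_layer("bn", ch = ch, momentum = momentum, eps = eps,
            gamma = rep(1, ch), beta = numeric(ch),
            run_mean = numeric(ch), run_var = rep(1, ch),
            ggamma = NULL, gbeta = NULL)
}

layer_relu <- function() new_layer("relu")
layer_sigmoid <- function() new_layer("sigmoid")

# stride-1 pooling pads bottom/right by k-1 so the spatial size is preserved
layer_maxpool <- function(k = 2, stride = 1) {
  new_layer("maxpool", k = as.integer(k), stride = as.integer(stride),
            pad = if (stride == 1) as.integer(k - 1) else 0L)
}

layer_forward <- function(layer, x, training = FALSE) {
  x <- as_chw(x)
  switch(layer$type,
    conv = {
      y <- ms_conv_fwd(x, layer$W, layer$b, layer$kernel[1], layer$kernel[2],
                       layer$stride, layer$pad[1], layer$pad[2],
                       layer$dilation)
      list(out = y, cache = if (training) list(x = x) else NULL)
    },
    tconv = {
      oH <- layer$stride * dim(x)[1]
      oW <- layer$stride * dim(x)[2]
      y <- ms_tconv_fwd(x, layer$W, layer$b, layer$kernel[1],
                        layer$kernel[2], layer$stride, layer$pad, oH, oW)
      list(out = y, cache = if (training) list(x = x) else NULL)
    },
    bn = bn_forward(layer, x, training),
    relu = list(out = pmax(x, 0), cache = if (training) list(pos = x > 0)),
    sigmoid = {
      y <- 1 / (1 + exp(-x))
      list(out = y, cache = if (training) list(y = y))
    },
    maxpool = {
      r <- ms_maxpool_fwd(x, layer$k, layer$stride, layer$pad)
      list(out = r$out,
           cache = if (training) list(argmax = r$argmax, dims = dim(x)))
    },
    stop("unknown layer type: ", layer$type))
}

bn_forward <- function(layer, x, training) {
  d <- dim(x); n <- d[1] * d[2]
  xm <- matrix(x, n, d[3])
  if (training) {
    mu <- colMeans(xm)
    xc <- sweep(xm, 2, mu)
    v <- colMeans(xc^2)
    layer$run_mean <- layer$momentum * layer$run_mean + (1 - layer$momentum) * mu
    layer$run_var <- layer$momentum * layer$run_var + (1 - layer$momentum) * v
  } else {
    mu <- layer$run_mean
    v <- layer$run_var
    xc <- sweep(xm, 2, mu)
  }
  inv_sd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xc, 2, inv_sd, `*`)
  y <- sweep(sweep(xhat, 2, layer$gamma, `*`), 2, layer$beta, `+`)
  list(out = array(y, dim = d),
       cache = if (training) list(xhat = xhat, inv_sd = inv_sd, dims = d))
}

# Accumulates parameter gradients into the layer and returns dx.
layer_backward <- function(layer, cache, dy) {
  dy <- as_chw(dy)
  switch(layer$type,
    conv = {
      g <- ms_conv_bwd(cache$x, dy, layer$W, layer$kernel[1],
                       layer$kernel[2], layer$stride, layer$pad[1],
                       layer$pad[2], layer$dilation)
      accum_grad(layer, "gW", g$dW); accum_grad(layer, "gb", as.numeric(g$db))
      g$dx
    },
    tconv = {
      g <- ms_tconv_bwd(cache$x, dy, layer$W, layer$kernel[1],
                        layer$kernel[2], layer$stride, layer$pad)
      accum_grad(layer, "gW", g$dW); accum_grad(layer, "gb", as.numeric(g$db))
      g$dx
    },
    bn = {
      d <- cache$dims; n <- d[1] * d[2]
      dym <- matrix(dy, n, d[3])
      dgamma <- colSums(dym * cache$xhat)
      dbeta <- colSums(dym)
      accum_grad(layer, "ggamma", dgamma); accum_grad(layer, "gbeta", dbeta)
      dxhat <- sweep(dym, 2, layer$gamma, `*`)
      t1 <- sweep(dxhat, 2, colMeans(dxhat))
      t2 <- sweep(cache$xhat, 2, colMeans(dxhat * cache$xhat), `*`)
      dx <- sweep(t1 - t2, 2, cache$inv_sd, `*`)
      array(dx, dim = d)
    },
    relu = dy * cache$pos,
    sigmoid = dy * cache$y * (1 - cache$y),
    maxpool = ms_maxpool_bwd(dy, cache$argmax, cache$dims[1], cache$dims[2],
                             cache$dims[3]),
    stop("unknown layer type: ", layer$type))
}

accum_grad <- function(layer, slot, g) {
  cur <- get(slot, envir = layer)
  assign(slot, if (is.null(cur)) g else cur + g, envir = layer)
}

layer_param_names <- function(layer) {
  switch(layer$type, conv = , tconv = c("W", "b"),
         bn = c("gamma", "beta"), character())
}

layer_grad_names <- function(layer) {
  switch(layer$type, conv = , tconv = c("gW", "gb"),
         bn = c("ggamma", "gbeta"), character())
}

layer_zero_grads <- function(layer) {
  for (g in layer_grad_names(layer)) assign(g, NULL, envir = layer)
  invisible(layer)
}

# Adam with decoupled L2 (weight decay applied to conv/tconv weight matrices
# only, directly on the parameter, not through the moment estimates).
layer_adam_step <- function(layer, lr, l2, beta1 = 0.9, beta2 = 0.999,
                            eps = 1e-8, scale = 1) {
  pn <- layer_param_names(layer)
  gn <- layer_grad_names(layer)
  if (!length(pn)) return(invisible(layer))
  if (is.null(layer$adam_t)) layer$adam_t <- 0L
  layer$adam_t <- layer$adam_t + 1L
  t <- layer$adam_t
  for (i in seq_along(pn)) {
    g <- get(gn[i], envir = layer)
    if (is.null(g)) next
    g <- g * scale
    mslot <- paste0("adam_m_", pn[i]); vslot <- paste0("adam_v_", pn[i])
    m <- if (is.null(layer[[mslot]])) g * 0 else layer[[mslot]]
    v <- if (is.null(layer[[vslot]])) g * 0 else layer[[vslot]]
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g^2
    mhat <- m / (1 - beta1^t)
    vhat <- v / (1 - beta2^t)
    p <- get(pn[i], envir = layer)
    p <- p - lr * mhat / (sqrt(vhat) + eps)
    if (l2 > 0 && pn[i] == "W") p <- p - lr * l2 * p
    assign(pn[i], p, envir = layer)
    layer[[mslot]] <- m
    layer[[vslot]] <- v
  }
  invisible(layer)
}
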