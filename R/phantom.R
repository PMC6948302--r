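#' Specify a synthetic low-contrast phantom
#'
#' Defines the statistical regime of a synthetic segmentation phantom: a small
#' number of blurred elliptical foreground blobs over a textured background,
#' with additive Gaussian noise and a smooth low-frequency intensity
#' inhomogeneity (bias field) as is typical of MRI. The defaults describe the
#' low-contrast regime the package's validation protocol trains on: a
#' foreground/background mean-intensity gap of 0.3 in normalized units with
#' noise SD 0.2, so the single-pixel signal-to-noise ratio is well below what
#' simple thresholding can segment.
#'
#' @param grid_size Pixels per side (scalar, 2D) or per axis (length-3, 3D).
#'   Every axis must be at least 16 and divisible by 16 so that the default
#'   network's four spatial halvings stay integral.
#' @param n_blobs Number of foreground components (>= 1).
#' @param contrast Foreground-minus-background mean intensity gap, in
#'   normalized units (> 0). The generator calibrates the clean image so the
#'   gap between mask-foreground and mask-background mean intensities equals
#'   this value exactly before noise.
#' @param noise_sd Additive Gaussian noise standard deviation (>= 0).
#' @param blur_sigma Boundary blur width in pixels applied to the rasterized
#'   blobs, emulating partial-volume blurred tissue boundaries.
#' @param bias_amplitude Peak-to-peak amplitude of the smooth intensity
#'   inhomogeneity field.
#' @param seed Integer randomness seed; identical specs reproduce identical
#'   phantoms bit for bit.
#' @return An object of class `ms_phantom_spec`.
#' @seealso [generate_phantom()], [generate_dataset()]
#' @export
phantom_spec <- function(grid_size = 64, n_blobs = 3, contrast = 0.3,
                         noise_sd = 0.2, blur_sigma = 1.5,
                         bias_amplitude = 0.2, seed = 1) {
  if (!length(grid_size) %in% c(1L, 3L))
    ms_stop("msunet_config_error",
            "grid_size must be a scalar (2D) or length-3 vector (3D)")
  if (any(grid_size < 16) || any(grid_size %% 16 != 0))
    ms_stop("msunet_config_error",
            "every grid_size axis must be >= 16 and divisible by 16")
  if (contrast <= 0) ms_stop("msunet_config_error", "contrast must be > 0")
  if (noise_sd < 0) ms_stop("msunet_config_error", "noise_sd must be >= 0")
  if (n_blobs < 1) ms_stop("msunet_config_error", "n_blobs must be >= 1")
  structure(list(grid_size = as.integer(grid_size),
                 n_blobs = as.integer(n_blobs), contrast = contrast,
                 noise_sd = noise_sd, blur_sigma = blur_sigma,
                 bias_amplitude = bias_amplitude, seed = as.integer(seed)),
            class = "ms_phantom_spec")
}

# Low-order cosine bias field scaled to a given peak-to-peak amplitude.
bias_field <- function(dims, amplitude) {
  if (amplitude <= 0) return(array(0, dim = dims))
  n_terms <- sample(2:4, 1)
  grids <- lapply(dims, function(n) (seq_len(n) - 1) / n)
  f <- array(0, dim = dims)
  for (t in seq_len(n_terms)) {
    freqs <- sample(1:2, length(dims), replace = TRUE)
    phases <- runif(length(dims), 0, 2 * pi)
    term <- Reduce(function(acc, ax) {
      v <- cos(2 * pi * freqs[ax] * grids[[ax]] + phases[ax])
      sweep_axis(acc, v, ax, dims)
    }, seq_along(dims), init = array(1, dim = dims))
    f <- f + runif(1, 0.5, 1) * term
  }
  rng <- range(f)
  if (diff(rng) < .Machine$double.eps) return(array(0, dim = dims))
  (f - mean(rng)) * (amplitude / diff(rng))
}

# multiply array `acc` by vector `v` broadcast along axis `ax`
sweep_axis <- function(acc, v, ax, dims) {
  perm <- c(ax, setdiff(seq_along(dims), ax))
  a <- aperm(acc, perm)
  a <- a * v
  aperm(a, order(perm))
}

# Rasterize one random ellipse/ellipsoid into a binary array.
raster_blob <- function(dims) {
  nd <- length(dims)
  ctr <- vapply(dims, function(n) runif(1, 0.25 * n, 0.75 * n), 0)
  rad <- vapply(dims, function(n) runif(1, 0.06 * n, 0.12 * n), 0)
  theta <- runif(1, 0, pi)
  idx <- lapply(dims, seq_len)
  if (nd == 2) {
    x <- outer(idx[[1]] - ctr[1], rep(1, dims[2]))
    y <- outer(rep(1, dims[1]), idx[[2]] - ctr[2])
    xr <- cos(theta) * x - sin(theta) * y
    yr <- sin(theta) * x + cos(theta) * y
    (xr / rad[1])^2 + (yr / rad[2])^2 <= 1
  } else {
    x <- array(rep(idx[[1]] - ctr[1], times = dims[2] * dims[3]), dim = dims)
    y <- array(rep(rep(idx[[2]] - ctr[2], each = dims[1]), times = dims[3]),
               dim = dims)
    z <- array(rep(idx[[3]] - ctr[3], each = dims[1] * dims[2]), dim = dims)
    xr <- cos(theta) * x - sin(theta) * y
    yr <- sin(theta) * x + cos(theta) * y
    (xr / rad[1])^2 + (yr / rad[2])^2 + (z / rad[3])^2 <= 1
  }
}

#' Generate one phantom image with its paired ground-truth mask
#'
#' Draws `n_blobs` randomly placed, sized and oriented ellipses (2D) or
#' ellipsoids (3D), rasterizes their union as the binary mask, blurs the blob
#' profile by `blur_sigma` to soften boundaries, adds a smooth bias field, and
#' calibrates the clean foreground amplitude so that the mean intensity of
#' mask-foreground pixels exceeds that of background pixels by exactly
#' `contrast` before noise. Additive Gaussian noise of SD `noise_sd` is then
#' applied. The whole construction is a pure function of the spec.
#'
#' @param spec A [phantom_spec()].
#' @return A list of class `ms_phantom` with elements `image` (noisy image),
#'   `clean` (pre-noise image), `mask` (binary integer array) and `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "ms_phantom_spec"))
  dims <- if (length(spec$grid_size) == 1) rep(spec$grid_size, 2)
          else spec$grid_size
  with_seed(spec$seed, {
    mask <- array(FALSE, dim = dims)
    for (b in seq_len(spec$n_blobs)) mask <- mask | raster_blob(dims)
    if (!any(mask))
      ms_stop("msunet_config_error", "phantom has no foreground pixels")
    soft <- gaussian_blur(array(as.numeric(mask), dim = dims),
                          spec$blur_sigma)
    bias <- bias_field(dims, spec$bias_amplitude)
    # calibrate amplitude so the pre-noise FG/BG mean gap equals `contrast`
    gap_soft <- mean(soft[mask]) - mean(soft[!mask])
    gap_bias <- mean(bias[mask]) - mean(bias[!mask])
    amp <- (spec$contrast - gap_bias) / gap_soft
    clean <- bias + amp * soft
    image <- clean + if (spec$noise_sd > 0)
      array(rnorm(length(clean), 0, spec$noise_sd), dim = dims) else 0
    structure(list(image = drop2(image, dims), clean = drop2(clean, dims),
                   mask = drop2(array(as.integer(mask), dim = dims), dims),
                   spec = spec),
              class = "ms_phantom")
  })
}

drop2 <- function(x, dims) {
  if (length(dims) == 2) matrix(x, dims[1], dims[2]) else x
}

#' Generate a seeded collection of phantom image/mask pairs
#'
#' Each pair is generated from a child seed derived deterministically from
#' `(spec$seed, index)`, so the collection is reproducible bit for bit while
#' every member differs.
#'
#' @param spec A [phantom_spec()]; its `seed` is the base seed.
#' @param n Number of pairs (>= 1).
#' @return A list of `n` [generate_phantom()] results.
#' @export
generate_dataset <- function(spec, n) {
  stopifnot(inherits(spec, "ms_phantom_spec"))
  if (n < 1) ms_stop("msunet_config_error", "n must be >= 1")
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- as.integer((spec$seed * 10007 + i * 7919) %% .Machine$integer.max)
    generate_phantom(s)
  })
}
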