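# Shared helpers: scoped RNG, separable Gaussian blur, bilinear/nearest
# resampling, channel concatenation.

# Evaluate `code` under a given seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

ms_stop <- function(class, msg, ...) {
  stop(structure(class = c(class, "msunet_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1), ...)))
}

# Row-stochastic 1D blur matrix with truncated-Gaussian rows (radius 3*sigma).
# Truncation at the border is renormalized so constant signals are preserved.
blur_matrix <- function(n, sigma) {
  if (sigma <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  B <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - r):(i + r)
    ok <- j >= 1 & j <= n
    w <- k[ok]
    B[i, j[ok]] <- w / sum(w)
  }
  B
}

# Separable Gaussian blur of a 2D matrix or 3D array (axis-wise for 3D).
gaussian_blur <- function(x, sigma) {
  if (sigma <= 0) return(x)
  d <- dim(x)
  if (length(d) == 2) {
    blur_matrix(d[1], sigma) %*% x %*% t(blur_matrix(d[2], sigma))
  } else if (length(d) == 3) {
    B1 <- blur_matrix(d[1], sigma); B2 <- blur_matrix(d[2], sigma)
    B3 <- blur_matrix(d[3], sigma)
    for (k in seq_len(d[3])) x[, , k] <- B1 %*% x[, , k] %*% t(B2)
    # blur along the third axis
    m <- matrix(x, nrow = d[1] * d[2], ncol = d[3])
    array(m %*% t(B3), dim = d)
  } else {
    ms_stop("msunet_geometry_error", "gaussian_blur expects a 2D or 3D array")
  }
}

# Sample a 2D image at fractional (row, col) source coordinates.
# coords: list(r =, c =) matrices congruent with the output grid.
resample2d <- function(img, coords, interp = c("bilinear", "nearest"),
                       fill = 0) {
  interp <- match.arg(interp)
  H <- nrow(img); W <- ncol(img)
  r <- coords$r; cc <- coords$c
  if (interp == "nearest") {
    ri <- round(r); ci <- round(cc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W
    out <- matrix(fill, nrow(r), ncol(r))
    out[ok] <- img[cbind(ri[ok], ci[ok])]
    return(out)
  }
  r0 <- floor(r); c0 <- floor(cc)
  fr <- r - r0; fc <- cc - c0
  out <- matrix(0, nrow(r), ncol(r))
  wsum <- matrix(0, nrow(r), ncol(r))
  for (dr in 0:1) for (dc in 0:1) {
    ri <- r0 + dr; ci <- c0 + dc
    w <- (if (dr == 0) 1 - fr else fr) * (if (dc == 0) 1 - fc else fc)
    ok <- ri >= 1 & ri <= H & ci >= 1 & ci <= W & w > 0
    out[ok] <- out[ok] + w[ok] * img[cbind(ri[ok], ci[ok])]
    wsum[ok] <- wsum[ok] + w[ok]
  }
  # positions whose 4-neighbourhood lies fully outside get the fill value
  out[wsum == 0] <- fill
  inb <- wsum > 0 & wsum < 1
  out[inb] <- out[inb] + (1 - wsum[inb]) * fill
  out
}

# Target-grid coordinates for a rotation (degrees, about the image centre)
# followed by a translation of (dr, dc) pixels: returns source coordinates.
affine_coords <- function(H, W, angle_deg = 0, dr = 0, dc = 0) {
  tr <- matrix(rep(seq_len(H), W), H, W)
  tc <- matrix(rep(seq_len(W), each = H), H, W)
  # invert the forward map: un-translate, then rotate by -angle about centre
  yr <- tr - dr; yc <- tc - dc
  if (angle_deg != 0) {
    a <- -angle_deg * pi / 180
    cy <- (H + 1) / 2; cx <- (W + 1) / 2
    ry <- yr - cy; rx <- yc - cx
    yr <- cy + cos(a) * ry - sin(a) * rx
    yc <- cx + sin(a) * ry + cos(a) * rx
  }
  list(r = yr, c = yc)
}

# Concatenate [H, W, C_i] arrays (or matrices, treated as C = 1) on channels.
concat_channels <- function(...) {
  xs <- lapply(list(...), as_chw)
  d1 <- dim(xs[[1]])
  for (x in xs) {
    if (!all(dim(x)[1:2] == d1[1:2]))
      ms_stop("msunet_geometry_error",
              "channel concatenation requires equal spatial sizes")
  }
  array(unlist(xs, use.names = FALSE),
        dim = c(d1[1], d1[2], sum(vapply(xs, function(x) dim(x)[3], 0))))
}

as_chw <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}
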