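#' Specify paired image/mask augmentation
#'
#' The five expansion transforms applied jointly to an image and its mask:
#' vertical flip, horizontal flip, random-angle rotation, random translation
#' and elastic deformation. Geometric parameters are sampled once per call
#' and applied identically to image and mask; images are resampled
#' bilinearly, masks with nearest-neighbour so they stay strictly binary.
#'
#' @param methods Subset of `c("vertical_flip", "horizontal_flip",
#'   "random_rotation", "random_translation", "elastic_deformation")`.
#' @param rotation_range Maximum absolute rotation in degrees (default 15).
#' @param translation_range Maximum translation as a fraction of the image
#'   extent, in `[0, 1)` (default 0.1); offsets are sampled in whole pixels.
#' @param elastic_alpha Elastic displacement magnitude in pixels.
#' @param elastic_sigma Elastic displacement smoothness in pixels.
#' @param seed Integer seed; identical seeds reproduce identical output.
#' @return An object of class `ms_augmentation_spec`.
#' @export
augmentation_spec <- function(methods = c("vertical_flip", "horizontal_flip",
                                          "random_rotation",
                                          "random_translation",
                                          "elastic_deformation"),
                              rotation_range = 15, translation_range = 0.1,
                              elastic_alpha = 10, elastic_sigma = 4,
                              seed = 1) {
  all_m <- c("vertical_flip", "horizontal_flip", "random_rotation",
             "random_translation", "elastic_deformation")
  if (length(methods) == 0)
    ms_stop("msunet_config_error", "methods must be non-empty")
  bad <- setdiff(methods, all_m)
  if (length(bad))
    ms_stop("msunet_config_error",
            paste("unknown augmentation method:", paste(bad, collapse = ", ")))
  if (rotation_range < 0)
    ms_stop("msunet_config_error", "rotation_range must be >= 0")
  if (translation_range < 0 || translation_range >= 1)
    ms_stop("msunet_config_error", "translation_range must be in [0, 1)")
  structure(list(methods = methods, rotation_range = rotation_range,
                 translation_range = translation_range,
                 elastic_alpha = elastic_alpha,
                 elastic_sigma = elastic_sigma, seed = as.integer(seed)),
            class = "ms_augmentation_spec")
}

# Sample the geometric parameters for one augment_pair call. Exposed
# internally so tests can recompute the expected transform from the seed.
sample_augment_params <- function(spec, H, W) {
  with_seed(spec$seed, {
    p <- list()
    if ("random_rotation" %in% spec$methods)
      p$angle <- runif(1, -spec$rotation_range, spec$rotation_range)
    if ("random_translation" %in% spec$methods) {
      mr <- floor(spec$translation_range * H)
      mc <- floor(spec$translation_range * W)
      p$dr <- sample(seq(-mr, mr), 1)
      p$dc <- sample(seq(-mc, mc), 1)
    }
    if ("elastic_deformation" %in% spec$methods) {
      p$field_r <- gaussian_blur(matrix(runif(H * W, -1, 1), H, W),
                                 spec$elastic_sigma) * spec$elastic_alpha
      p$field_c <- gaussian_blur(matrix(runif(H * W, -1, 1), H, W),
                                 spec$elastic_sigma) * spec$elastic_alpha
    }
    p
  })
}

#' Apply the configured augmentation transforms to an image/mask pair
#'
#' @param image Numeric matrix.
#' @param mask Congruent binary mask.
#' @param spec An [augmentation_spec()].
#' @return `list(image =, mask =)` with the input shape; the mask stays
#'   strictly binary.
#' @export
augment_pair <- function(image, mask, spec) {
  stopifnot(inherits(spec, "ms_augmentation_spec"))
  if (!all(dim(image) == dim(mask)))
    ms_stop("msunet_congruence_error", "image and mask shapes differ")
  H <- nrow(image); W <- ncol(image)
  p <- sample_augment_params(spec, H, W)
  img <- image; msk <- mask
  if ("vertical_flip" %in% spec$methods) {
    img <- img[H:1, , drop = FALSE]; msk <- msk[H:1, , drop = FALSE]
  }
  if ("horizontal_flip" %in% spec$methods) {
    img <- img[, W:1, drop = FALSE]; msk <- msk[, W:1, drop = FALSE]
  }
  angle <- if (is.null(p$angle)) 0 else p$angle
  dr <- if (is.null(p$dr)) 0 else p$dr
  dc <- if (is.null(p$dc)) 0 else p$dc
  if (angle != 0 || dr != 0 || dc != 0) {
    co <- affine_coords(H, W, angle, dr, dc)
    img <- resample2d(img, co, "bilinear", fill = 0)
    msk <- resample2d(msk, co, "nearest", fill = 0)
  }
  if (!is.null(p$field_r)) {
    tr <- matrix(rep(seq_len(H), W), H, W)
    tc <- matrix(rep(seq_len(W), each = H), H, W)
    co <- list(r = tr + p$field_r, c = tc + p$field_c)
    img <- resample2d(img, co, "bilinear", fill = 0)
    msk <- resample2d(msk, co, "nearest", fill = 0)
  }
  storage.mode(msk) <- "integer"
  list(image = img, mask = msk)
}

rot90_cw <- function(m) t(m[nrow(m):1, , drop = FALSE])
rot90_ccw <- function(m) t(m)[ncol(m):1, , drop = FALSE]
rot180 <- function(m) m[nrow(m):1, ncol(m):1, drop = FALSE]

#' Expand a dataset by right-angle rotations
#'
#' The default scheme maps each input pair to four: the original, a 90-degree
#' left rotation, a 90-degree right rotation, and a 180-degree rotation —
#' the minimal rotation-only scheme that quadruples the collection (100
#' source pairs become 400). Right-angle rotations permute pixels exactly, so
#' intensity multisets and foreground counts are preserved. Each derived pair
#' records its source index and variant for provenance-aware splitting.
#'
#' @param pairs Non-empty list of `list(image =, mask =)` pairs (phantoms
#'   from [generate_phantom()] work directly).
#' @param scheme Character vector of variants from `c("identity", "rot90",
#'   "rot270", "rot180")`, applied in order.
#' @return List of `length(pairs) * length(scheme)` pairs, each with
#'   `source` (input index) and `variant` fields.
#' @export
expand_dataset <- function(pairs,
                           scheme = c("identity", "rot90", "rot270",
                                      "rot180")) {
  if (length(pairs) == 0)
    ms_stop("msunet_config_error", "input collection is empty")
  fns <- list(identity = identity, rot90 = rot90_ccw, rot270 = rot90_cw,
              rot180 = rot180)
  bad <- setdiff(scheme, names(fns))
  if (length(bad))
    ms_stop("msunet_config_error",
            paste("unknown expansion variant:", paste(bad, collapse = ", ")))
  out <- vector("list", length(pairs) * length(scheme))
  k <- 0L
  for (i in seq_along(pairs)) {
    for (v in scheme) {
      k <- k + 1L
      out[[k]] <- list(image = fns[[v]](pairs[[i]]$image),
                       mask = fns[[v]](pairs[[i]]$mask),
                       source = i, variant = v)
    }
  }
  out
}
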