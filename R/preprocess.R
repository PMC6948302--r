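#' Specify a region-of-interest crop
#'
#' @param target_shape Target extent in pixels per axis. Defaults to the
#'   standard 128 x 128 2D patch; use `c(80, 80, 40)` for the 3D hippocampus
#'   ROI convention.
#' @param center Crop centre in 1-based voxel coordinates, or `"auto"`: the
#'   foreground centroid when a mask is supplied, else the volume centre. Auto
#'   centres are clamped minimally so the window lies inside the volume.
#' @return An object of class `ms_crop_spec`.
#' @export
crop_spec <- function(target_shape = c(128, 128), center = "auto") {
  if (any(target_shape < 1))
    ms_stop("msunet_config_error", "target dimensions must be positive")
  structure(list(target_shape = as.integer(target_shape), center = center),
            class = "ms_crop_spec")
}

#' Extract a region of interest from an image (and optional mask)
#'
#' Crops image and mask with identical half-open bounds around the requested
#' centre. Pixel values are never altered, only extent. When a mask is
#' supplied its entire foreground must lie inside the crop window.
#'
#' @param image Numeric matrix (2D) or 3D array.
#' @param crop A [crop_spec()]; every target dimension must not exceed the
#'   corresponding input dimension.
#' @param mask Optional congruent binary mask; cropped with the same bounds.
#' @return `list(image =, mask =)` (mask `NULL` when not supplied).
#' @export
extract_roi <- function(image, crop, mask = NULL) {
  stopifnot(inherits(crop, "ms_crop_spec"))
  din <- dim(image)
  tgt <- crop$target_shape
  if (length(tgt) != length(din))
    ms_stop("msunet_dimension_error",
            "crop dimensionality does not match the image")
  if (any(tgt > din))
    ms_stop("msunet_dimension_error",
            "crop target exceeds the input extent")
  if (!is.null(mask) && !all(dim(mask) == din))
    ms_stop("msunet_congruence_error", "image and mask shapes differ")
  ctr <- crop$center
  if (identical(ctr, "auto")) {
    ctr <- if (!is.null(mask) && any(mask > 0)) {
      idx <- which(mask > 0, arr.ind = TRUE)
      colMeans(idx)
    } else (din + 1) / 2
  }
  # half-open [start, start + tgt); clamp the centre toward the interior
  start <- floor(ctr - tgt / 2) + 1L
  start <- pmax(1, pmin(start, din - tgt + 1))
  idx <- lapply(seq_along(din), function(a) start[a]:(start[a] + tgt[a] - 1))
  out_img <- do.call(`[`, c(list(image), idx, list(drop = FALSE)))
  dim(out_img) <- tgt
  out_mask <- NULL
  if (!is.null(mask)) {
    out_mask <- do.call(`[`, c(list(mask), idx, list(drop = FALSE)))
    dim(out_mask) <- tgt
    if (sum(out_mask > 0) != sum(mask > 0))
      ms_stop("msunet_crop_coverage_error",
              "mask foreground is not containable in the crop window")
  }
  list(image = out_img, mask = out_mask)
}

#' Gray-level regularization: subtract the mean, divide by the SD
#'
#' Standardizes an image to mean 0 and population standard deviation 1,
#' computed over the image's own pixels (per-image normalization). Idempotent
#' within floating tolerance.
#'
#' @param image Numeric array with at least 2 pixels and nonzero SD.
#' @param stats Optional `list(mean =, sd =)` to apply dataset-global
#'   statistics instead of the image's own.
#' @return The standardized image, same shape.
#' @export
normalize_gray <- function(image, stats = NULL) {
  if (length(image) < 2)
    ms_stop("msunet_degenerate_input_error", "image must have >= 2 pixels")
  m <- if (is.null(stats)) mean(image) else stats$mean
  s <- if (is.null(stats)) sqrt(mean((image - m)^2)) else stats$sd
  if (s <= .Machine$double.eps)
    ms_stop("msunet_degenerate_input_error",
            "constant image: standard deviation is zero")
  (image - m) / s
}
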