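# Image and manifest I/O: PNG for 2D slices, NIfTI for volumes.

#' Read a grayscale image (PNG slice or NIfTI volume)
#'
#' @param path File path; `.png` is read as a 2D matrix (multi-channel PNGs
#'   are averaged to grayscale), `.nii`/`.nii.gz` as a numeric array.
#' @param mask Interpret the file as a binary mask (values > 0.5 become 1).
#' @return Numeric matrix/array (integer when `mask = TRUE`).
#' @export
read_image <- function(path, mask = FALSE) {
  x <- if (grepl("\\.png$", path, ignore.case = TRUE)) {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3) apply(a[, , 1:min(3, dim(a)[3]), drop = FALSE],
                                   c(1, 2), mean) else a
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    arr <- RNifti::readNifti(path)
    array(as.numeric(arr), dim = dim(arr))
  } else {
    ms_stop("msunet_data_error", paste("unsupported image format:", path))
  }
  if (mask) {
    x <- (x > 0.5) * 1L
    storage.mode(x) <- "integer"
  }
  x
}

#' Write a grayscale image or mask
#'
#' PNG output is grayscale; images are affinely rescaled to `[0, 1]`
#' (masks are written as exact 0/1 rasters). NIfTI output stores raw values.
#'
#' @param x Numeric matrix (PNG) or array (NIfTI).
#' @param path Destination ending in `.png`, `.nii` or `.nii.gz`.
#' @param mask Whether `x` is a binary mask.
#' @export
write_image <- function(x, path, mask = FALSE) {
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    m <- as.matrix(x)
    if (mask) {
      m <- (m > 0) * 1
    } else {
      rng <- range(m)
      m <- if (diff(rng) > 0) (m - rng[1]) / diff(rng) else m * 0
    }
    png::writePNG(m, path, dpi = NULL)
  } else if (grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)) {
    RNifti::writeNifti(RNifti::asNifti(x), path)
  } else {
    ms_stop("msunet_data_error", paste("unsupported image format:", path))
  }
  invisible(path)
}

#' Write a run manifest
#'
#' Records the configuration snapshot, seed, input/artifact paths with MD5
#' checksums and the package version, so a run can be reproduced exactly
#' from its manifest.
#'
#' @param path Output JSON path.
#' @param config Configuration list to snapshot.
#' @param seed Integer seed of the run.
#' @param inputs,artifacts Character vectors of file paths.
#' @export
write_manifest <- function(path, config, seed, inputs = character(),
                           artifacts = character()) {
  checksum <- function(fs) {
    if (!length(fs)) return(list())
    md5 <- tools::md5sum(fs)
    mapply(function(f, h) list(path = f, md5 = unname(h)),
           fs, md5, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  }
  obj <- list(tool = "msunet",
              version = as.character(utils::packageVersion("msunet")),
              seed = seed, config = config,
              inputs = checksum(inputs), artifacts = checksum(artifacts))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
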