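# Masked-region colour extraction: read an 8-bit photograph and a greyscale
# mask, convert every included pixel sRGB -> XYZ -> Lab, and average in Lab.

#' Coerce or read an 8-bit sRGB image
#'
#' Accepts a file path (PNG, TIFF or JPEG) or a height x width x 3 numeric
#' array of 8-bit channel values. The result carries the colour-space tag
#' `"sRGB-8bit"`; all downstream colorimetry assumes it.
#'
#' @param x File path or h x w x 3 array with values in \[0, 255\].
#' @return An object of class `rgb_image`: the integer-valued array with
#'   attribute `colour_space = "sRGB-8bit"`.
#' @export
as_rgb_image <- function(x) {
  if (is.character(x)) x <- .read_image_array(x) * 255
  if (!is.array(x) || length(dim(x)) != 3 || dim(x)[3] != 3) {
    stop("an RGB image must be a height x width x 3 array")
  }
  if (any(!is.finite(x)) || any(x < 0) || any(x > 255)) {
    stop("RGB channel values must be finite and in [0, 255]")
  }
  x <- round(x)
  structure(x, colour_space = "sRGB-8bit", class = "rgb_image")
}

# read PNG/TIFF/JPEG into a [0,1] array (greyscale matrix or h x w x ch)
.read_image_array <- function(path) {
  if (!file.exists(path)) stop("image file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = jpeg::readJPEG(path),
    stop("unsupported image format: .", ext, " (expected png/tiff/jpeg)")
  )
  # drop an alpha channel if present
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3, drop = FALSE]
  img
}

#' Load a greyscale mask image as a pixel-inclusion map
#'
#' A pixel belongs to the region iff its grey value exceeds 127 on the 0-255
#' scale (so 128 and above are included, 127 and below excluded).
#'
#' @param mask File path to a single-channel 8-bit image, or a numeric matrix
#'   of grey values in \[0, 255\].
#' @return An object of class `region_mask`: list with `include` (logical
#'   matrix) and `n_pixels` (count of included pixels).
#' @export
load_mask <- function(mask) {
  if (is.character(mask)) {
    arr <- .read_image_array(mask)
    if (length(dim(arr)) == 3) {
      ch <- dim(arr)[3]
      for (k in seq_len(ch)[-1]) {
        if (any(arr[, , k] != arr[, , 1])) {
          stop("mask image must be single-channel (channels differ)")
        }
      }
      arr <- arr[, , 1]
    }
    mask <- round(arr * 255)
  }
  if (!is.matrix(mask) || any(!is.finite(mask)) || any(mask < 0) || any(mask > 255)) {
    stop("a mask must be a numeric matrix of grey values in [0, 255]")
  }
  include <- mask > 127
  structure(list(include = include, n_pixels = sum(include)),
            class = "region_mask")
}

#' @export
print.region_mask <- function(x, ...) {
  cat("region_mask:", nrow(x$include), "x", ncol(x$include),
      "with", x$n_pixels, "included pixels\n")
  invisible(x)
}

.check_mask_image <- function(image, mask) {
  di <- dim(image)[1:2]
  dm <- dim(mask$include)
  if (!identical(as.integer(di), as.integer(dm))) {
    stop(sprintf("mask dimensions (%d x %d) do not match image (%d x %d)",
                 dm[1], dm[2], di[1], di[2]))
  }
}

#' Mean CIELAB colour over a masked region
#'
#' Each included pixel is converted sRGB -> XYZ -> L*a*b* individually and the
#' unweighted arithmetic mean of L*, a*, b* over the region is returned. The
#' average is taken in Lab space, after conversion, not on raw RGB.
#'
#' @param image An `rgb_image` (or anything [as_rgb_image()] accepts).
#' @param mask A `region_mask` (or anything [load_mask()] accepts).
#' @return Named numeric vector `c(L, a, b)`.
#' @export
mean_region_colour <- function(image, mask) {
  image <- as_rgb_image(image)
  if (!inherits(mask, "region_mask")) mask <- load_mask(mask)
  .check_mask_image(image, mask)
  if (mask$n_pixels == 0) stop("empty region: mask includes no pixels")
  idx <- which(mask$include)
  np <- length(idx)
  rgb <- cbind(image[, , 1][idx], image[, , 2][idx], image[, , 3][idx])
  lab <- .xyz_to_lab_mat(.srgb_to_xyz_mat(rgb))
  out <- colMeans(lab)
  names(out) <- c("L", "a", "b")
  out
}

#' Colour attributes of one photograph
#'
#' Composes the full extraction for one image/mask pair: region-mean L*, a*,
#' b* via [mean_region_colour()], then hue and chroma computed from the mean
#' a* and b* (not averaged per pixel).
#'
#' @inheritParams mean_region_colour
#' @return An object of class `colour_attributes`: named numeric vector
#'   `c(L, a, b, h, C)` with attribute `n_pixels`. Hue is in degrees.
#' @export
attributes_for_image <- function(image, mask) {
  if (!inherits(mask, "region_mask")) mask <- load_mask(mask)
  lab <- mean_region_colour(image, mask)
  hc <- hue_chroma(lab["a"], lab["b"])
  out <- c(lab, h = unname(hc$h), C = unname(hc$C))
  structure(out, n_pixels = mask$n_pixels, class = "colour_attributes")
}

#' @export
print.colour_attributes <- function(x, digits = 4, ...) {
  cat("colour_attributes (", attr(x, "n_pixels"), " pixels):\n", sep = "")
  print(round(unclass(x), digits))
  invisible(x)
}

#' Batch colour extraction over a manifest
#'
#' Runs [attributes_for_image()] for every row of an experiment manifest,
#' optionally calibrating each image first.
#'
#' @param manifest Data frame with columns `image_id`, `image` (path) and
#'   `mask` (path); any further columns are carried through.
#' @param calibration Optional `calibration_transform` applied to every image
#'   before extraction (see [fit_calibration()]).
#' @return Data frame with the manifest's extra columns plus `image_id`,
#'   `n_pixels`, `L`, `a`, `b`, `h_deg`, `C`.
#' @export
extract_attributes <- function(manifest, calibration = NULL) {
  req <- c("image_id", "image", "mask")
  if (!all(req %in% names(manifest))) {
    stop("manifest must have columns: ", paste(req, collapse = ", "))
  }
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    img <- as_rgb_image(manifest$image[i])
    if (!is.null(calibration)) img <- apply_calibration(img, calibration)
    att <- attributes_for_image(img, load_mask(manifest$mask[i]))
    data.frame(image_id = manifest$image_id[i],
               n_pixels = attr(att, "n_pixels"),
               L = att[["L"]], a = att[["a"]], b = att[["b"]],
               h_deg = att[["h"]], C = att[["C"]])
  })
  out <- do.call(rbind, rows)
  extra <- setdiff(names(manifest), c(req, names(out)))
  if (length(extra)) out <- cbind(out, manifest[, extra, drop = FALSE])
  rownames(out) <- NULL
  out
}
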