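# Chart-based colour calibration: a 3x3 linear map fitted in linearised RGB
# between observed and nominal chart-patch colours, applied to whole images
# before extraction. Models an illumination/colour cast as a linear change of
# the light reaching the sensor; no offset term, so black stays black.

#' Fit a linear calibration transform from colour-chart patches
#'
#' Least-squares fit of a 3x3 matrix `M` such that `M %*% observed_linear`
#' approximates `reference_linear` for every patch, where both sides are the
#' sRGB-decoded (linear-light) channel values. At least 3 patches of full
#' rank are required; a 24-patch chart is recommended.
#'
#' @param measurements Data frame with columns `patch_id`, `obs_r`, `obs_g`,
#'   `obs_b`, `ref_r`, `ref_g`, `ref_b` (8-bit values 0-255).
#' @return Object of class `calibration_transform`: list with `matrix` (3x3)
#'   and `fit_residual` (root-mean-square patch error in linear RGB after
#'   correction).
#' @export
fit_calibration <- function(measurements) {
  req <- c("patch_id", "obs_r", "obs_g", "obs_b", "ref_r", "ref_g", "ref_b")
  if (!all(req %in% names(measurements))) {
    stop("chart measurements must have columns: ", paste(req, collapse = ", "))
  }
  if (anyDuplicated(measurements$patch_id)) stop("patch_ids must be unique")
  n <- nrow(measurements)
  if (n < 3) stop("underdetermined calibration: need at least 3 patches, got ", n)
  obs <- srgb_decode(as.matrix(measurements[, c("obs_r", "obs_g", "obs_b")]) / 255)
  ref <- srgb_decode(as.matrix(measurements[, c("ref_r", "ref_g", "ref_b")]) / 255)
  if (qr(obs)$rank < 3) {
    stop("underdetermined calibration: patch design is rank-deficient")
  }
  # rows of obs are observations; corrected = obs %*% t(M)
  Mt <- qr.solve(obs, ref)
  M <- t(Mt)
  dimnames(M) <- NULL
  resid <- ref - obs %*% Mt
  structure(list(matrix = M, fit_residual = sqrt(mean(resid^2))),
            class = "calibration_transform")
}

#' @export
print.calibration_transform <- function(x, ...) {
  cat("calibration_transform (linear RGB, 3x3):\n")
  print(round(x$matrix, 6))
  cat("RMS patch residual:", signif(x$fit_residual, 4), "\n")
  invisible(x)
}

#' Apply a calibration transform to an image
#'
#' Per pixel: decode sRGB to linear light, multiply by the calibration
#' matrix, clip to \[0, 1\] (never wrap or renormalise), re-encode and
#' quantise back to 8 bits. Dimensions are preserved.
#'
#' @param image An `rgb_image` (or anything [as_rgb_image()] accepts).
#' @param transform A `calibration_transform` from [fit_calibration()].
#' @return Calibrated `rgb_image`.
#' @export
apply_calibration <- function(image, transform) {
  image <- as_rgb_image(image)
  if (!inherits(transform, "calibration_transform")) {
    stop("transform must be a calibration_transform")
  }
  d <- dim(image)
  flat <- matrix(as.numeric(image), ncol = 3)
  lin <- srgb_decode(flat / 255) %*% t(transform$matrix)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  out <- round(srgb_encode(lin) * 255)
  as_rgb_image(array(out, dim = d))
}

#' Read chart measurements from CSV
#'
#' @param path CSV with columns `patch_id, obs_r, obs_g, obs_b, ref_r,
#'   ref_g, ref_b`.
#' @return Data frame of chart measurements.
#' @export
read_chart_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Serialise / restore a calibration transform as JSON
#'
#' @param transform A `calibration_transform`.
#' @param path Output (or input) JSON path.
#' @name calibration_json
#' @export
write_calibration_json <- function(transform, path) {
  jsonlite::write_json(
    list(matrix = transform$matrix, fit_residual = transform$fit_residual),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}

#' @rdname calibration_json
#' @export
read_calibration_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- x$matrix
  if (!is.matrix(m)) m <- matrix(unlist(m), 3, 3, byrow = TRUE)
  structure(list(matrix = m, fit_residual = as.numeric(x$fit_residual)),
            class = "calibration_transform")
}
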