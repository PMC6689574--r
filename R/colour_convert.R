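# sRGB (IEC 61966-2-1, D65 / 2 degree observer) <-> XYZ <-> CIE 1976 L*a*b*.
#
# The linear-RGB -> XYZ matrix is the classic 6-decimal sRGB/D65 matrix; its
# middle row sums to exactly 1, so the 8-bit white (255,255,255) has Y = 1.
# The reference white is defined as the matrix row sums, which makes white map
# to L* = 100, a* = b* = 0 exactly rather than within rounding.

.SRGB_XYZ <- matrix(c(
  0.412453, 0.357580, 0.180423,
  0.212671, 0.715160, 0.072169,
  0.019334, 0.119193, 0.950227
), nrow = 3, byrow = TRUE)

.XYZ_SRGB <- solve(.SRGB_XYZ)

#' D65 reference white tristimulus values
#'
#' The white point used throughout the package: the XYZ of the sRGB white
#' (255,255,255), i.e. the row sums of the adopted sRGB matrix, with Y = 1.
#'
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
d65_white <- function() {
  w <- as.vector(.SRGB_XYZ %*% c(1, 1, 1))
  names(w) <- c("X", "Y", "Z")
  w
}

# sRGB transfer function (decode: gamma-compressed [0,1] -> linear [0,1])
srgb_decode <- function(v) {
  ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)
}

srgb_encode <- function(v) {
  ifelse(v <= 0.0031308, 12.92 * v, 1.055 * v^(1 / 2.4) - 0.055)
}

# n x 3 matrix of 0-255 channels -> n x 3 XYZ
.srgb_to_xyz_mat <- function(rgb) {
  if (any(!is.finite(rgb)) || any(rgb < 0) || any(rgb > 255)) {
    stop("sRGB channel values must be finite and in [0, 255]")
  }
  lin <- srgb_decode(rgb / 255)
  lin %*% t(.SRGB_XYZ)
}

# n x 3 XYZ -> n x 3 Lab
.xyz_to_lab_mat <- function(xyz, white = d65_white()) {
  if (white[2] <= 0) stop("reference white must have Y > 0")
  if (any(xyz < -1e-9)) {
    stop("negative tristimulus values beyond tolerance (-1e-9)")
  }
  xyz[xyz < 0] <- 0
  t_ <- sweep(xyz, 2, unname(white), "/")
  delta <- 6 / 29
  f <- ifelse(t_ > delta^3, t_^(1 / 3), t_ / (3 * delta^2) + 4 / 29)
  cbind(
    L = 116 * f[, 2] - 16,
    a = 500 * (f[, 1] - f[, 2]),
    b = 200 * (f[, 2] - f[, 3])
  )
}

.lab_to_xyz_mat <- function(lab, white = d65_white()) {
  delta <- 6 / 29
  fy <- (lab[, 1] + 16) / 116
  fx <- fy + lab[, 2] / 500
  fz <- fy - lab[, 3] / 200
  finv <- function(f) ifelse(f > delta, f^3, 3 * delta^2 * (f - 4 / 29))
  xyz <- cbind(finv(fx), finv(fy), finv(fz))
  sweep(xyz, 2, unname(white), "*")
}

# n x 3 Lab -> n x 3 0-1 encoded sRGB (clipped to gamut, never wrapped)
.lab_to_srgb01_mat <- function(lab, white = d65_white()) {
  lin <- .lab_to_xyz_mat(lab, white) %*% t(.XYZ_SRGB)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  srgb_encode(lin)
}

#' Convert one sRGB pixel to XYZ tristimulus values
#'
#' Scales the 8-bit channels to \[0,1\], decodes the two-piece sRGB transfer
#' function (threshold 0.04045, exponent 2.4) and applies the sRGB/D65
#' linear-RGB to XYZ matrix. Y is normalised so the reference white has Y = 1.
#'
#' @param rgb Numeric vector of three channel values in \[0, 255\].
#' @return Named numeric vector `c(X, Y, Z)`.
#' @examples
#' srgb_to_xyz(c(255, 255, 255))["Y"]  # exactly 1
#' @export
srgb_to_xyz <- function(rgb) {
  stopifnot(length(rgb) == 3)
  out <- .srgb_to_xyz_mat(matrix(as.numeric(rgb), nrow = 1))[1, ]
  names(out) <- c("X", "Y", "Z")
  out
}

#' Convert XYZ tristimulus values to CIE 1976 L*a*b*
#'
#' Standard CIELAB formulas with the two-branch cube-root/linear function
#' (delta = 6/29, offset 4/29). L* runs from 0 (black) to 100 (the reference
#' white); a* is the red/green opponent axis, b* the yellow/blue axis.
#'
#' @param xyz Numeric vector `c(X, Y, Z)`.
#' @param white Reference white, default [d65_white()].
#' @return Named numeric vector `c(L, a, b)`.
#' @export
xyz_to_lab <- function(xyz, white = d65_white()) {
  stopifnot(length(xyz) == 3)
  out <- .xyz_to_lab_mat(matrix(as.numeric(xyz), nrow = 1), white)[1, ]
  names(out) <- c("L", "a", "b")
  out
}

#' Convert CIE L*a*b* back to XYZ
#'
#' Exact inverse of [xyz_to_lab()]; used for round-trip verification and for
#' rendering synthetic fixtures from Lab targets.
#'
#' @param lab Numeric vector `c(L, a, b)`.
#' @param white Reference white, default [d65_white()].
#' @return Named numeric vector `c(X, Y, Z)`.
#' @export
lab_to_xyz <- function(lab, white = d65_white()) {
  stopifnot(length(lab) == 3)
  out <- .lab_to_xyz_mat(matrix(as.numeric(lab), nrow = 1), white)[1, ]
  names(out) <- c("X", "Y", "Z")
  out
}

#' Hue angle and chroma from opponent coordinates
#'
#' Chroma is the radial distance in the a*-b* plane, `C = sqrt(a^2 + b^2)`;
#' hue is `atan2(b, a)` in degrees wrapped into \[0, 360). An achromatic
#' colour (C = 0) reports h = 0 by convention.
#'
#' @param a,b Opponent-axis values (vectorised).
#' @return A list with numeric components `h` (degrees) and `C`.
#' @examples
#' hue_chroma(3, 4)   # C = 5
#' hue_chroma(0, 1)   # h = 90
#' @export
hue_chroma <- function(a, b) {
  stopifnot(length(a) == length(b))
  C <- sqrt(a^2 + b^2)
  h <- atan2(b, a) * 180 / pi
  h <- h %% 360
  h[C == 0] <- 0
  list(h = h, C = C)
}
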