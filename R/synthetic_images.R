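# Synthetic image fixtures: an elliptical "fish" of known Lab colour with
# optional mottling on a uniform background, plus the matching binary mask.
# The recorded ground truth is recomputed from the rendered 8-bit pixels (not
# the pre-quantisation target), so extraction can be checked bit-exactly.

#' Specification for a synthetic fish image
#'
#' @param width,height Image size in pixels.
#' @param centre Ellipse centre `c(row, col)`; default image centre.
#' @param axes Ellipse semi-axes `c(row, col)` in pixels.
#' @param base_lab Body colour as `c(L, a, b)`.
#' @param mottle_sd Per-pixel zero-mean Gaussian perturbation SDs in Lab,
#'   `c(L, a, b)`; emulates the species' mottled grey patterning.
#' @param background_lab Background colour as `c(L, a, b)`.
#' @param seed Integer seed; the fixture is a pure function of the spec.
#' @return Object of class `fish_image_spec`.
#' @export
fish_image_spec <- function(width = 64, height = 64,
                            centre = c(height / 2 + 0.5, width / 2 + 0.5),
                            axes = c(height / 4, width / 3),
                            base_lab = c(55, 2, 8),
                            mottle_sd = c(6, 1, 2),
                            background_lab = c(25, 0, 0),
                            seed = 1L) {
  spec <- list(width = as.integer(width), height = as.integer(height),
               centre = centre, axes = axes, base_lab = base_lab,
               mottle_sd = mottle_sd, background_lab = background_lab,
               seed = as.integer(seed))
  if (spec$centre[1] - spec$axes[1] < 1 || spec$centre[1] + spec$axes[1] > spec$height ||
      spec$centre[2] - spec$axes[2] < 1 || spec$centre[2] + spec$axes[2] > spec$width) {
    stop("fish ellipse must lie strictly inside the image")
  }
  structure(spec, class = "fish_image_spec")
}

# independent of colour_core's extraction path: region mean recomputed here
# directly from the rendered 8-bit values
.truth_from_rendered <- function(img, include) {
  idx <- which(include)
  rgb <- cbind(img[, , 1][idx], img[, , 2][idx], img[, , 3][idx])
  lab <- colMeans(.xyz_to_lab_mat(.srgb_to_xyz_mat(rgb)))
  hc <- hue_chroma(lab[2], lab[3])
  structure(c(L = lab[[1]], a = lab[[2]], b = lab[[3]],
              h = hc$h, C = hc$C),
            n_pixels = length(idx), class = "colour_attributes")
}

#' Render a synthetic fish photograph with ground truth
#'
#' Pixels inside the ellipse get the base Lab colour plus mottle noise; the
#' rest get the background colour. Lab values are converted to sRGB, clipped
#' to gamut and quantised to 8 bits. The mask is 255 inside the ellipse and 0
#' outside. Deterministic given the spec's seed.
#'
#' @param spec A [fish_image_spec()].
#' @return List with `image` (`rgb_image`), `mask` (grey-value matrix,
#'   0/255), `truth` (`colour_attributes` of the rendered region) and `spec`.
#' @export
generate_fish_image <- function(spec = fish_image_spec()) {
  stopifnot(inherits(spec, "fish_image_spec"))
  h <- spec$height; w <- spec$width
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  include <- ((rows - spec$centre[1]) / spec$axes[1])^2 +
             ((cols - spec$centre[2]) / spec$axes[2])^2 <= 1
  n_in <- sum(include)

  lab <- matrix(spec$background_lab, h * w, 3, byrow = TRUE)
  rng <- .with_seed(spec$seed, {
    matrix(stats::rnorm(3 * n_in), n_in, 3)
  })
  body <- matrix(spec$base_lab, n_in, 3, byrow = TRUE) +
    sweep(rng, 2, spec$mottle_sd, "*")
  body[, 1] <- pmin(pmax(body[, 1], 0), 100)
  lab[which(include), ] <- body

  px <- round(.lab_to_srgb01_mat(lab) * 255)
  img <- as_rgb_image(array(px, dim = c(h, w, 3)))
  mask <- matrix(0, h, w)
  mask[include] <- 255
  list(image = img, mask = mask,
       truth = .truth_from_rendered(img, include), spec = spec)
}

# evaluate expr under a local RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Write a fish fixture to disk as lossless PNG files
#'
#' @param fixture Result of [generate_fish_image()].
#' @param dir Output directory.
#' @param id Basename for the files (`<id>.png`, `<id>_mask.png`).
#' @return Named character vector with `image` and `mask` paths.
#' @export
write_fish_fixture <- function(fixture, dir, id = "fish") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ipath <- file.path(dir, paste0(id, ".png"))
  mpath <- file.path(dir, paste0(id, "_mask.png"))
  png::writePNG(unclass(fixture$image) / 255, ipath)
  png::writePNG(fixture$mask / 255, mpath)
  c(image = ipath, mask = mpath)
}

# default 24-patch reference chart: 18 chromatic + 6 neutral patches spanning
# the sRGB gamut, loosely modelled on a standard photographic colour chart
.default_chart_reference <- function() {
  ref <- rbind(
    c(115,  82,  68), c(194, 150, 130), c( 98, 122, 157), c( 87, 108,  67),
    c(133, 128, 177), c(103, 189, 170), c(214, 126,  44), c( 80,  91, 166),
    c(193,  90,  99), c( 94,  60, 108), c(157, 188,  64), c(224, 163,  46),
    c( 56,  61, 150), c( 70, 148,  73), c(175,  54,  60), c(231, 199,  31),
    c(187,  86, 149), c(  8, 133, 161), c(243, 243, 242), c(200, 200, 200),
    c(160, 160, 160), c(122, 122, 121), c( 85,  85,  85), c( 52,  52,  52))
  data.frame(patch_id = sprintf("p%02d", seq_len(nrow(ref))),
             ref_r = ref[, 1], ref_g = ref[, 2], ref_b = ref[, 3])
}

#' Generate synthetic chart measurements under a known colour cast
#'
#' Applies `cast_matrix` to the reference patches in linear RGB, clips to
#' gamut and quantises to 8 bits, yielding the "observed" patch colours a
#' camera would record under that cast.
#'
#' @param cast_matrix Invertible 3x3 matrix acting on linear RGB; identity
#'   means no cast.
#' @param reference Data frame `patch_id, ref_r, ref_g, ref_b`; defaults to
#'   the built-in 24-patch chart.
#' @param quantise Round the observed values to whole 8-bit steps (what a
#'   camera records). `FALSE` keeps them continuous, emulating noiseless
#'   patch measurements; with no clipping the cast is then exactly
#'   invertible from the fixture.
#' @return Chart-measurement data frame suitable for [fit_calibration()].
#' @export
generate_chart_fixture <- function(cast_matrix = diag(3),
                                   reference = .default_chart_reference(),
                                   quantise = TRUE) {
  if (!is.matrix(cast_matrix) || !all(dim(cast_matrix) == c(3, 3))) {
    stop("cast_matrix must be 3x3")
  }
  if (abs(det(cast_matrix)) < 1e-8) stop("cast_matrix is singular")
  ref <- as.matrix(reference[, c("ref_r", "ref_g", "ref_b")])
  lin <- srgb_decode(ref / 255) %*% t(cast_matrix)
  lin[lin < 0] <- 0
  lin[lin > 1] <- 1
  obs <- srgb_encode(lin) * 255
  if (quantise) obs <- round(obs)
  data.frame(patch_id = reference$patch_id,
             obs_r = obs[, 1], obs_g = obs[, 2], obs_b = obs[, 3],
             ref_r = ref[, 1], ref_g = ref[, 2], ref_b = ref[, 3])
}
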