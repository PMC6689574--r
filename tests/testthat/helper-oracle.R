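# Brute-force per-pixel oracle for region-mean colour, written as plain
# scalar arithmetic so the vectorised extraction path can be checked
# against an independent implementation of the same colorimetric standard.

oracle_pixel_lab <- function(r, g, b) {
  dec <- function(u) {
    u <- u / 255
    if (u <= 0.04045) u / 12.92 else ((u + 0.055) / 1.055)^2.4
  }
  R <- dec(r); G <- dec(g); B <- dec(b)
  X <- 0.412453 * R + 0.357580 * G + 0.180423 * B
  Y <- 0.212671 * R + 0.715160 * G + 0.072169 * B
  Z <- 0.019334 * R + 0.119193 * G + 0.950227 * B
  wn <- c(0.412453 + 0.357580 + 0.180423,
          0.212671 + 0.715160 + 0.072169,
          0.019334 + 0.119193 + 0.950227)
  f <- function(t) if (t > (6 / 29)^3) t^(1 / 3) else t / (3 * (6 / 29)^2) + 4 / 29
  fx <- f(X / wn[1]); fy <- f(Y / wn[2]); fz <- f(Z / wn[3])
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

oracle_region_mean <- function(img, mask_grey) {
  acc <- c(0, 0, 0); n <- 0L
  for (i in seq_len(nrow(mask_grey))) {
    for (j in seq_len(ncol(mask_grey))) {
      if (mask_grey[i, j] > 127) {
        acc <- acc + oracle_pixel_lab(img[i, j, 1], img[i, j, 2], img[i, j, 3])
        n <- n + 1L
      }
    }
  }
  acc / n
}

random_image <- function(h, w) {
  as_rgb_image(array(sample(0:255, h * w * 3, replace = TRUE), dim = c(h, w, 3)))
}

random_mask_grey <- function(h, w, p_include = 0.5) {
  matrix(ifelse(stats::runif(h * w) < p_include,
                sample(128:255, h * w, replace = TRUE),
                sample(0:127, h * w, replace = TRUE)),
         h, w)
}

# uniform-colour image helper
uniform_image <- function(rgb, h = 4, w = 4) {
  as_rgb_image(array(rep(rgb, each = h * w), dim = c(h, w, 3)))
}

full_mask <- function(h = 4, w = 4) load_mask(matrix(255, h, w))
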