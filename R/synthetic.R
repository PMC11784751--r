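# Seeded synthetic grayscale image generator.
#
# Three regimes stand in for the imaging modalities a medical codec meets:
#  * smooth  — low-order 2-D polynomial illumination with mild additive
#              Gaussian noise (X-ray/CT-like large smooth structures);
#  * texture — a band-limited random field with sharp region edges
#              (complex-textured content);
#  * speckle — smooth base multiplied by unit-mean exponential noise, the
#              standard fully developed speckle model (ultrasound-like);
#  * mixed   — a region-wise composite of the three.
# Each image is fully determined by its spec (kind, size, seed, noise scale).

#' Generate one synthetic grayscale image
#'
#' @param kind `"smooth"`, `"texture"`, `"speckle"` or `"mixed"`.
#' @param height,width Image size in pixels, each `>= 16`.
#' @param seed Integer seed; the same spec always yields the same image.
#' @param noise_scale Scale of the regime's stochastic component
#'   (additive noise sd in gray levels for smooth/texture; unused scaling
#'   for speckle, whose multiplicative noise has fixed unit mean).
#' @return Integer-valued matrix in `[0, 255]`.
#' @export
generate_image <- function(kind = c("smooth", "texture", "speckle", "mixed"),
                           height = 64L, width = 64L, seed = 1L,
                           noise_scale = 2) {
  kind <- match.arg(kind)
  if (height < 16L || width < 16L) stop("dimensions must be >= 16")
  with_seed(seed, {
    img <- switch(kind,
      smooth = synth_smooth(height, width, noise_scale),
      texture = synth_texture(height, width, noise_scale),
      speckle = synth_speckle(height, width),
      mixed = synth_mixed(height, width, noise_scale)
    )
    matrix(pmin(pmax(round(img), 0), 255), height, width)
  })
}

poly_ramp <- function(h, w) {
  u <- matrix(seq(-1, 1, length.out = h), h, w)
  v <- matrix(seq(-1, 1, length.out = w), h, w, byrow = TRUE)
  co <- stats::runif(6, -1, 1)
  f <- co[1] + co[2] * u + co[3] * v + co[4] * u * v + co[5] * u^2 + co[6] * v^2
  (f - min(f)) / max(max(f) - min(f), 1e-9)
}

synth_smooth <- function(h, w, noise_scale) {
  40 + 175 * poly_ramp(h, w) + stats::rnorm(h * w, sd = noise_scale)
}

# Band-limited field: white noise smoothed with a small box filter, plus
# sharp edges from thresholding a second smooth field.
synth_texture <- function(h, w, noise_scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  k <- 2L
  zs <- box_blur(z, k)
  edges <- poly_ramp(h, w) > stats::runif(1, 0.35, 0.65)
  base <- 60 + 120 * edges
  base + 55 * zs / max(abs(zs)) + stats::rnorm(h * w, sd = noise_scale)
}

# Fully developed speckle: unit-mean exponential intensity noise made
# spatially correlated by a small point-spread-function blur (coherent
# imaging correlates neighboring resolution cells; the blurred field has a
# Gamma-like marginal, i.e. multi-look speckle).
synth_speckle <- function(h, w) {
  base <- 25 + 140 * poly_ramp(h, w)
  noise <- box_blur(matrix(stats::rexp(h * w, rate = 1), h, w), 1L)
  base * noise
}

synth_mixed <- function(h, w, noise_scale) {
  out <- synth_smooth(h, w, noise_scale)
  th <- h %/% 2L; tw <- w %/% 2L
  out[seq_len(th), tw + seq_len(w - tw)] <-
    synth_texture(h, w, noise_scale)[seq_len(th), tw + seq_len(w - tw)]
  out[th + seq_len(h - th), seq_len(tw)] <-
    synth_speckle(h, w)[th + seq_len(h - th), seq_len(tw)]
  out
}

box_blur <- function(z, k) {
  h <- nrow(z); w <- ncol(z)
  out <- matrix(0, h, w)
  cnt <- matrix(0, h, w)
  for (dy in -k:k) for (dx in -k:k) {
    ys <- pmin(pmax(seq_len(h) + dy, 1L), h)
    xs <- pmin(pmax(seq_len(w) + dx, 1L), w)
    out <- out + z[ys, xs]
    cnt <- cnt + 1
  }
  out / cnt
}

#' Generate a seeded dataset of synthetic images
#'
#' Images cycle over the requested regimes; the `"train"` and `"test"` splits
#' draw from disjoint seed ranges so held-out evaluation never sees a
#' training image.
#'
#' @param n Number of images.
#' @param kinds Regimes to cycle over.
#' @param seed Base seed.
#' @param height,width Image size.
#' @param split `"train"` or `"test"`.
#' @return List of pixel matrices.
#' @export
generate_dataset <- function(n, kinds = c("smooth", "texture", "speckle"),
                             seed = 1L, height = 64L, width = 64L,
                             split = c("train", "test")) {
  split <- match.arg(split)
  offset <- if (split == "train") 0L else 100000L
  lapply(seq_len(n), function(i) {
    generate_image(kinds[[(i - 1L) %% length(kinds) + 1L]], height, width,
                   seed = seed + offset + i)
  })
}
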