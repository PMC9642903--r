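#' Single-scale non-logarithmic Retinex baseline
#'
#' Per channel, `Retinex(x, y, s) = I(x, y) - (I * G)(x, y, s)` with the
#' surround kernel `G(x, y, s) = exp(-(x^2 + y^2) / s^2)` on the full image
#' support, normalized per pixel by the kernel mass falling inside the
#' image. That normalization is the one consistent reading of the
#' full-support formula: it makes a constant image map to exactly zero at
#' every pixel, and in the large-`s` limit the surround becomes the plain
#' image mean everywhere. Small `s` gives a high-pass response (colors only
#' near edges, achromatic in between); large `s` retains chromatic content.
#' The raw output is signed; `display = TRUE` adds a mid-gray 0.5 offset and
#' clips, the standard rendering of difference-of-Gaussian outputs.
#'
#' @param img `H x W x 3` array.
#' @param s spatial scale of the Gaussian surround (pixels), `> 0`.
#' @param display return the viewable mid-gray variant instead of signed
#'   values.
#' @return `H x W x 3` array (signed unless `display = TRUE`).
#' @export
retinex <- function(img, s, display = FALSE) {
  img <- as_rgb_image(img)
  if (!is.finite(s) || s <= 0) stop("s must be > 0", call. = FALSE)
  H <- dim(img)[1L]; W <- dim(img)[2L]
  if (max(H, W) > 512L)
    stop("full-support Retinex kernel capped at 512 px images", call. = FALSE)
  # separable full-support weights as Toeplitz matrices; the surround is
  # (Ky I Kx) / (row mass x column mass), so the in-image normalization
  # factorizes exactly
  Ky <- exp(-outer(seq_len(H), seq_len(H), "-")^2 / s^2)
  Kx <- exp(-outer(seq_len(W), seq_len(W), "-")^2 / s^2)
  denom <- outer(rowSums(Ky), rowSums(Kx))
  out <- img
  for (ch in 1:3)
    out[, , ch] <- img[, , ch] - (Ky %*% img[, , ch] %*% Kx) / denom
  if (display) out <- clip01(out + 0.5)
  out
}

#' Feature-distance metric specification
#'
#' The perceptual-distance contract: a pluggable feature extractor mapping
#' an image to a list of feature layers, per-layer weights, and a weighted
#' squared-L2 distance averaged over pixels. The shipped default extractor
#' is the identity (pixel space) with unit weight, which makes the distance
#' the mean over pixels of the squared channel-wise difference; learned
#' extractors can be plugged in through the same interface.
#'
#' @param extractor function(image) returning a list of numeric arrays
#'   (feature layers), each with pixels along the first two dimensions.
#' @param weights numeric vector of per-layer weights (recycled).
#' @return list of class `metric_spec`.
#' @export
metric_spec <- function(extractor = function(img) list(as_rgb_image(img)),
                        weights = 1) {
  stopifnot(is.function(extractor))
  structure(list(extractor = extractor, weights = weights),
            class = "metric_spec")
}

#' Perceptual distance between two images
#'
#' Computes the metric-spec distance: for each feature layer `l`,
#' the mean over pixels of `|| w_l * (Phi_l(a) - Phi_l(b)) ||^2`, summed over
#' layers. Nonnegative, symmetric, and zero iff the features agree (with the
#' default identity extractor, iff the images are equal).
#'
#' @param a,b images of equal shape.
#' @param metric a [metric_spec()].
#' @return numeric distance.
#' @export
perceptual_distance <- function(a, b, metric = metric_spec()) {
  stopifnot(inherits(metric, "metric_spec"))
  if (!identical(dim(as_rgb_image(a)), dim(as_rgb_image(b))))
    stop("images must share one shape", call. = FALSE)
  fa <- metric$extractor(a)
  fb <- metric$extractor(b)
  stopifnot(length(fa) == length(fb))
  w <- rep_len(metric$weights, length(fa))
  d <- 0
  for (l in seq_along(fa)) {
    df <- w[l] * (fa[[l]] - fb[[l]])
    n_px <- prod(dim(as.array(df))[1:2])
    d <- d + sum(df^2) / n_px
  }
  d
}

#' Mean chroma of a region
#'
#' Mean u'v' distance from the D65 achromatic point over the masked pixels;
#' 0 for a pure gray region. Pixels with undefined chromaticity (zero
#' luminance) are dropped; an all-undefined region is an error.
#'
#' @param img `H x W x 3` array in `[0, 1]` (clipped display values).
#' @param region_mask logical matrix; default the whole image.
#' @return numeric mean chroma distance.
#' @export
chroma_summary <- function(img, region_mask = NULL) {
  img <- clip01(as_rgb_image(img))
  m <- rgb_to_upvp(img)
  if (is.null(region_mask)) region_mask <- matrix(TRUE, dim(img)[1L], dim(img)[2L])
  region_mask <- region_mask & m$defined
  if (!any(region_mask)) stop("no masked pixel has defined chromaticity", call. = FALSE)
  ref <- d65_chromaticity()
  d <- sqrt((m$u_prime[region_mask] - ref[["u_prime"]])^2 +
              (m$v_prime[region_mask] - ref[["v_prime"]])^2)
  mean(d)
}
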