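#' The linear opponent color transformation matrix
#'
#' Maps an (R, G, B) pixel to the opponent triple (RG, BY, I): a red-green
#' difference, a blue-yellow difference, and the achromatic luminance
#' combination with the Rec. 601 weights a = 0.2989, b = 0.587, c = 0.114.
#'
#' @return a 3 x 3 numeric matrix with rows (RG, BY, I).
#' @export
opponent_matrix <- function() .opp$M

# Constants cached at load; the inverse is computed once and checked.
.opp <- local({
  a <- 0.2989; b <- 0.587; c <- 0.114
  M <- rbind(
    rg = c(1 / 2, -1 / 2, 0),
    by = c(1 / 6, 1 / 6, -2 / 6),
    i  = c(a, b, c)
  )
  colnames(M) <- c("r", "g", "b")
  Minv <- solve(M)
  stopifnot(max(abs(M %*% Minv - diag(3))) <= 1e-12)
  list(M = M, Minv = Minv, luma = c(a, b, c))
})

new_opponent_image <- function(rg, by, intensity) {
  stopifnot(identical(dim(rg), dim(by)), identical(dim(rg), dim(intensity)))
  structure(list(rg = rg, by = by, intensity = intensity),
            class = "opponent_image")
}

#' @export
print.opponent_image <- function(x, ...) {
  cat(sprintf("<opponent_image %d x %d>  rg [%.3g, %.3g]  by [%.3g, %.3g]  I [%.3g, %.3g]\n",
              nrow(x$rg), ncol(x$rg),
              min(x$rg), max(x$rg), min(x$by), max(x$by),
              min(x$intensity), max(x$intensity)))
  invisible(x)
}

#' Forward opponent transform of an RGB image
#'
#' Per-pixel matrix product with [opponent_matrix()]. The transform is exactly
#' linear; achromatic pixels map to `rg = by = 0`. For inputs in `[0, 1]` the
#' planes satisfy `rg` in \[-1/2, 1/2\], `by` in \[-1/3, 1/3\] and
#' `intensity` in \[0, 0.9999\].
#'
#' @param img `H x W x 3` array (see [as_rgb_image()]).
#' @return an `opponent_image`: list of matrices `rg`, `by`, `intensity`.
#' @export
rgb_to_opponent <- function(img) {
  img <- as_rgb_image(img)
  d <- dim(img)
  px <- matrix(img, d[1L] * d[2L], 3L)          # pixels x (r,g,b)
  opp <- px %*% t(.opp$M)
  new_opponent_image(
    rg = matrix(opp[, 1L], d[1L], d[2L]),
    by = matrix(opp[, 2L], d[1L], d[2L]),
    intensity = matrix(opp[, 3L], d[1L], d[2L])
  )
}

#' Inverse opponent transform
#'
#' Per-pixel product with the cached inverse of [opponent_matrix()]. Without
#' clipping the round trip `opponent_to_rgb(rgb_to_opponent(x))` is the
#' identity to machine precision; `clip = TRUE` clamps to `[0, 1]` and is
#' meant for final image export only, never inside the pipeline.
#'
#' @param opp an `opponent_image`, or a list with matrices `rg`, `by`,
#'   `intensity` (co-registered).
#' @param clip clamp the result into `[0, 1]`?
#' @return `H x W x 3` array.
#' @export
opponent_to_rgb <- function(opp, clip = FALSE) {
  stopifnot(all(c("rg", "by", "intensity") %in% names(opp)))
  d <- dim(opp$rg)
  stopifnot(identical(d, dim(opp$by)), identical(d, dim(opp$intensity)))
  px <- cbind(as.numeric(opp$rg), as.numeric(opp$by), as.numeric(opp$intensity))
  out <- px %*% t(.opp$Minv)
  img <- array(out, dim = c(d, 3L))
  if (clip) img <- clip01(img)
  img
}

# sRGB (D65) to CIE XYZ, IEC 61966-2-1 primaries.
.srgb_to_xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041
), 3L, 3L, byrow = TRUE)

srgb_decode <- function(v) ifelse(v <= 0.04045, v / 12.92, ((v + 0.055) / 1.055)^2.4)

#' CIE 1976 u'v' chromaticity of every pixel
#'
#' Standard chain sRGB -> linear RGB (gamma decode) -> XYZ (D65) -> u'v' with
#' `u' = 4X / (X + 15Y + 3Z)` and `v' = 9Y / (X + 15Y + 3Z)`. Pixels whose
#' denominator is zero (pure black) have no chromaticity; they are flagged in
#' `defined` and carry `NA` coordinates rather than silently propagating NaN.
#'
#' @param img `H x W x 3` array with values in `[0, 1]`.
#' @param gamma_decode apply the sRGB transfer function before the linear
#'   conversion (default `TRUE`; set `FALSE` if the image is already linear).
#' @return list with matrices `u_prime`, `v_prime` and logical `defined`.
#' @export
rgb_to_upvp <- function(img, gamma_decode = TRUE) {
  img <- as_rgb_image(img)
  if (min(img) < 0 || max(img) > 1)
    stop("chromaticity conversion expects values in [0, 1]; clip first", call. = FALSE)
  d <- dim(img)
  px <- matrix(img, d[1L] * d[2L], 3L)
  if (gamma_decode) px <- srgb_decode(px)
  xyz <- px %*% t(.srgb_to_xyz)
  den <- xyz[, 1L] + 15 * xyz[, 2L] + 3 * xyz[, 3L]
  ok <- den > 0
  up <- vp <- rep(NA_real_, nrow(xyz))
  up[ok] <- 4 * xyz[ok, 1L] / den[ok]
  vp[ok] <- 9 * xyz[ok, 2L] / den[ok]
  list(u_prime = matrix(up, d[1L], d[2L]),
       v_prime = matrix(vp, d[1L], d[2L]),
       defined = matrix(ok, d[1L], d[2L]))
}

#' The D65 achromatic point in u'v'
#'
#' Chromaticity of the reference white `(1, 1, 1)`; approximately
#' (0.1978, 0.4683). Distances from this point quantify chroma.
#'
#' @return named numeric vector `c(u_prime, v_prime)`.
#' @export
d65_chromaticity <- function() {
  m <- rgb_to_upvp(rgb_pixel(1, 1, 1))
  c(u_prime = m$u_prime[1L, 1L], v_prime = m$v_prime[1L, 1L])
}

#' Euclidean distance between chromaticity points
#'
#' Operates elementwise on matching vectors/matrices of coordinates; errors on
#' undefined (NA) inputs rather than propagating them.
#'
#' @param pt,ref each a list or named vector with `u_prime` and `v_prime`.
#' @return nonnegative numeric distance(s) in the u'v' plane.
#' @export
chroma_distance <- function(pt, ref) {
  up <- pt[["u_prime"]]; vp <- pt[["v_prime"]]
  ur <- ref[["u_prime"]]; vr <- ref[["v_prime"]]
  if (anyNA(up) || anyNA(vp) || anyNA(ur) || anyNA(vr))
    stop("chroma_distance: undefined chromaticity in input", call. = FALSE)
  sqrt((up - ur)^2 + (vp - vr)^2)
}
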