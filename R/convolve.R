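# Small exact 2-D convolution with replicate-edge padding.
#
# Both model kernels (Gaussian, discrete Laplacian) are point-symmetric, so
# convolution and correlation coincide; the code below computes the
# correlation form. Replicate padding makes constant images exact fixed
# points of the normalized Gaussian and gives the Laplacian zero response on
# constants everywhere, which the model's algebraic identities rely on.

pad_replicate <- function(x, pr, pc) {
  ri <- c(rep(1L, pr), seq_len(nrow(x)), rep(nrow(x), pr))
  ci <- c(rep(1L, pc), seq_len(ncol(x)), rep(ncol(x), pc))
  x[ri, ci, drop = FALSE]
}

#' Convolve a plane with a small kernel, replicate-edge boundary
#'
#' Direct (non-FFT) correlation-form convolution; exact for the symmetric
#' kernels used by the receptive-field models. The kernel must be odd-sized
#' in both dimensions and no larger than the plane.
#'
#' @param x numeric matrix.
#' @param k odd-sized numeric kernel matrix.
#' @return matrix of the same shape as `x`.
#' @export
conv2_replicate <- function(x, k) {
  x <- as.matrix(x); k <- as.matrix(k)
  if (nrow(k) %% 2L == 0L || ncol(k) %% 2L == 0L)
    stop("kernel must be odd-sized", call. = FALSE)
  if (nrow(k) > nrow(x) || ncol(k) > ncol(x))
    stop("kernel larger than image", call. = FALSE)
  pr <- (nrow(k) - 1L) %/% 2L
  pc <- (ncol(k) - 1L) %/% 2L
  p <- pad_replicate(x, pr, pc)
  H <- nrow(x); W <- ncol(x)
  out <- matrix(0, H, W)
  for (i in seq_len(nrow(k))) {
    for (j in seq_len(ncol(k))) {
      if (k[i, j] != 0)
        out <- out + k[i, j] * p[i:(i + H - 1L), j:(j + W - 1L)]
    }
  }
  out
}

# Separable convolution: 1-D kernel down columns then across rows.
conv_sep_replicate <- function(x, ky, kx = ky) {
  x <- as.matrix(x)
  hy <- (length(ky) - 1L) %/% 2L
  hx <- (length(kx) - 1L) %/% 2L
  if (length(ky) %% 2L == 0L || length(kx) %% 2L == 0L)
    stop("kernel must be odd-sized", call. = FALSE)
  if (length(ky) > nrow(x) * 2L - 1L || length(kx) > ncol(x) * 2L - 1L)
    stop("kernel larger than supported for this image", call. = FALSE)
  H <- nrow(x); W <- ncol(x)
  p <- x[c(rep(1L, hy), seq_len(H), rep(H, hy)), , drop = FALSE]
  tmp <- matrix(0, H, W)
  for (i in seq_along(ky)) if (ky[i] != 0)
    tmp <- tmp + ky[i] * p[i:(i + H - 1L), , drop = FALSE]
  p <- tmp[, c(rep(1L, hx), seq_len(W), rep(W, hx)), drop = FALSE]
  out <- matrix(0, H, W)
  for (j in seq_along(kx)) if (kx[j] != 0)
    out <- out + kx[j] * p[, j:(j + W - 1L), drop = FALSE]
  out
}

# Normalized 1-D Gaussian samples on -half:half; `denom` selects between the
# conventional 2*sigma^2 exponent and the Retinex s^2 form.
gauss1d <- function(half, sigma, denom = c("two_sigma_sq", "s_sq")) {
  denom <- match.arg(denom)
  d <- seq.int(-half, half)
  w <- switch(denom,
    two_sigma_sq = exp(-d^2 / (2 * sigma^2)),
    s_sq = exp(-d^2 / sigma^2)
  )
  w / sum(w)
}

# 1-D Gaussian smoothing of a vector with replicate ends (profile smoothing).
smooth1d_gaussian <- function(v, sigma) {
  if (sigma <= 0) return(v)
  half <- max(1L, ceiling(4 * sigma))
  k <- gauss1d(half, sigma)
  n <- length(v)
  p <- c(rep(v[1L], half), v, rep(v[n], half))
  out <- numeric(n)
  for (i in seq_along(k)) out <- out + k[i] * p[i:(i + n - 1L)]
  out
}
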