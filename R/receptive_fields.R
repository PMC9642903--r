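#' Gaussian receptive-field kernel specification
#'
#' The single-opponent (SO) channels are modeled as low-pass filters: each
#' opponent plane is convolved with a normalized Gaussian of window size `W`
#' (odd, pixels) and width `sigma` (pixels). The model-execution default is
#' `W = 21`, `sigma = 5`; the narrower parameter-evaluation setting
#' `W = 11`, `sigma = 3` is available as the `"narrow"` preset.
#'
#' @param W odd window size in pixels, `>= 3`.
#' @param sigma Gaussian width in pixels, `> 0`.
#' @param preset `"default"` (21, 5) or `"narrow"` (11, 3); explicit `W`
#'   and `sigma` override the preset.
#' @return list with `W` and `sigma`, class `gaussian_kernel_spec`.
#' @export
gaussian_kernel_spec <- function(W = NULL, sigma = NULL,
                                 preset = c("default", "narrow")) {
  preset <- match.arg(preset)
  p <- switch(preset, default = list(W = 21L, sigma = 5), narrow = list(W = 11L, sigma = 3))
  if (is.null(W)) W <- p$W
  if (is.null(sigma)) sigma <- p$sigma
  W <- as.integer(W)
  if (W < 3L || W %% 2L == 0L) stop("W must be odd and >= 3", call. = FALSE)
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(W = W, sigma = sigma), class = "gaussian_kernel_spec")
}

#' Realize the normalized Gaussian kernel
#'
#' `kernel(x, y)` is proportional to `exp(-(x^2 + y^2) / (2 sigma^2))` on the
#' support `s = -floor(W/2) ... floor(W/2)` and is normalized by the sum over
#' that support, so the entries sum to exactly 1.
#'
#' @param spec a [gaussian_kernel_spec()].
#' @return `W x W` numeric matrix summing to 1.
#' @export
make_gaussian_kernel <- function(spec) {
  stopifnot(inherits(spec, "gaussian_kernel_spec"))
  half <- spec$W %/% 2L
  d <- seq.int(-half, half)
  w <- exp(-d^2 / (2 * spec$sigma^2))
  k <- outer(w, w)
  k / sum(k)
}

#' The discrete Laplacian kernel of the double-opponent model
#'
#' The fixed 3 x 3 stencil `(0,-1,0; -1,4,-1; 0,-1,0)`. Entries sum to zero
#' and the kernel is point-symmetric. Note the sign convention: this is the
#' negative of the analyst's five-point Laplacian, so a bright center on a
#' dark ground responds positively; the filling-in solver consumes the
#' resulting source with the matching sign.
#'
#' @return 3 x 3 numeric matrix.
#' @export
laplacian_kernel <- function() {
  matrix(c(0, -1, 0, -1, 4, -1, 0, -1, 0), 3L, 3L, byrow = TRUE)
}

#' Single-opponent (low-pass) channel responses
#'
#' Convolves each opponent plane with the normalized Gaussian (replicate-edge
#' boundary, so a constant plane is an exact fixed point). Implemented as two
#' separable 1-D passes, which is exactly equivalent to the 2-D kernel because
#' the normalization factorizes.
#'
#' @param opp an `opponent_image` from [rgb_to_opponent()].
#' @param spec a [gaussian_kernel_spec()].
#' @return list of matrices `so_rg`, `so_by`, `i_lpf`.
#' @export
single_opponent <- function(opp, spec = gaussian_kernel_spec()) {
  stopifnot(inherits(spec, "gaussian_kernel_spec"))
  if (spec$W > nrow(opp$rg) || spec$W > ncol(opp$rg))
    stop("kernel larger than image", call. = FALSE)
  k1 <- gauss1d(spec$W %/% 2L, spec$sigma)
  list(
    so_rg = conv_sep_replicate(opp$rg, k1),
    so_by = conv_sep_replicate(opp$by, k1),
    i_lpf = conv_sep_replicate(opp$intensity, k1)
  )
}

#' Double-opponent (chromatic edge) channel responses
#'
#' Convolves each opponent plane with [laplacian_kernel()] under the
#' replicate-edge boundary rule. Constant planes and linear ramps give zero
#' response in the interior.
#'
#' @param opp an `opponent_image`.
#' @return list of matrices `do_rg`, `do_by`, `i_onoff`.
#' @export
double_opponent <- function(opp) {
  if (nrow(opp$rg) < 3L || ncol(opp$rg) < 3L)
    stop("image smaller than 3 x 3", call. = FALSE)
  L <- laplacian_kernel()
  list(
    do_rg = conv2_replicate(opp$rg, L),
    do_by = conv2_replicate(opp$by, L),
    i_onoff = conv2_replicate(opp$intensity, L)
  )
}

#' Full channel set feeding the perception network
#'
#' The five-plus-one filtered planes of the model front end: the three
#' low-pass single-opponent planes and the three Laplacian double-opponent
#' planes, all co-registered with the input.
#'
#' @param img `H x W x 3` RGB array, or an `opponent_image`.
#' @param spec a [gaussian_kernel_spec()].
#' @return list with `so_rg`, `so_by`, `i_lpf`, `do_rg`, `do_by`, `i_onoff`
#'   and the `opponent` planes used, class `channel_set`.
#' @export
channel_responses <- function(img, spec = gaussian_kernel_spec()) {
  opp <- if (inherits(img, "opponent_image")) img else rgb_to_opponent(img)
  out <- c(single_opponent(opp, spec), double_opponent(opp), list(opponent = opp))
  structure(out, class = "channel_set")
}

#' @export
print.channel_set <- function(x, ...) {
  cat(sprintf("<channel_set %d x %d> planes: so_rg so_by i_lpf do_rg do_by i_onoff\n",
              nrow(x$so_rg), ncol(x$so_rg)))
  invisible(x)
}
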