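# Fixtures built in code; no stored data.

# Smooth nonnegative plane that is exactly zero on its one-pixel border:
# squared sine bump, optionally modulated by seeded low-frequency noise.
smooth_zero_border_plane <- function(H = 32L, W = H, amplitude = 0.5) {
  outer(sin(pi * (0:(H - 1)) / (H - 1)), sin(pi * (0:(W - 1)) / (W - 1)))^2 *
    amplitude
}

# RGB image with zero border built from three scaled copies of the bump.
smooth_zero_border_image <- function(H = 32L) {
  b <- smooth_zero_border_plane(H, H, 1)
  img <- array(0, dim = c(H, H, 3L))
  img[, , 1L] <- 0.8 * b
  img[, , 2L] <- 0.3 * b
  img[, , 3L] <- 0.5 * b
  img
}

# Random RGB image in [0, 1] under a local seed.
random_rgb_image <- function(H, W = H, seed = 1L) {
  set.seed(seed)
  array(runif(H * W * 3), dim = c(H, W, 3L))
}

red_square_stimulus <- function(side = 20L, canvas = 64L,
                                background = c(0.5, 0.5, 0.5)) {
  make_square(side, canvas = c(canvas, canvas), fill_rgb = c(1, 0, 0),
              background_rgb = background)
}
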