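#' Validate and coerce an RGB image array
#'
#' The package represents a stimulus or a perceived image as a plain numeric
#' `H x W x 3` array, row-major with origin at the top-left and channel order
#' R, G, B. Values are reflectance-like and are expected in `[0, 1]` on input;
#' intermediate pipeline stages may leave that range and are only clipped at
#' final export.
#'
#' @param x numeric `H x W x 3` array (or an `H x W` matrix, promoted to a
#'   gray image by channel replication).
#' @return the validated array, invisibly unchanged.
#' @export
as_rgb_image <- function(x) {
  if (is.matrix(x)) x <- array(rep(x, 3L), dim = c(dim(x), 3L))
  if (!is.array(x) || length(dim(x)) != 3L || dim(x)[3L] != 3L)
    stop("an RGB image must be an H x W x 3 numeric array", call. = FALSE)
  if (!is.numeric(x)) stop("image values must be numeric", call. = FALSE)
  if (!all(is.finite(x))) stop("image values must all be finite", call. = FALSE)
  x
}

#' Build a 1 x 1 x 3 image from a single RGB triple
#'
#' Convenience for pixel-level checks of the color transforms.
#'
#' @param r,g,b channel values.
#' @return a `1 x 1 x 3` array.
#' @export
rgb_pixel <- function(r, g, b) array(c(r, g, b), dim = c(1L, 1L, 3L))

#' Clip an image (or plane) into the unit interval
#'
#' Clipping is applied only at final export so algebraic identities hold
#' inside the pipeline.
#'
#' @param x numeric array.
#' @return `x` with values clamped to `[0, 1]`.
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

#' Read a PNG file as an RGB image in `[0, 1]`
#'
#' 8- and 16-bit PNGs are mapped linearly to `[0, 1]` by the decoder.
#' Grayscale files are promoted to three identical channels; an alpha channel
#' is dropped.
#'
#' @param path file path.
#' @return `H x W x 3` array.
#' @export
read_image_png <- function(path) {
  x <- png::readPNG(path)
  if (is.matrix(x)) return(as_rgb_image(x))
  if (dim(x)[3L] >= 4L) x <- x[, , 1:3, drop = FALSE]
  if (dim(x)[3L] == 1L) return(as_rgb_image(x[, , 1L]))
  as_rgb_image(x)
}

#' Write an RGB image to a PNG file
#'
#' Values are clipped to `[0, 1]` at export (the only place the package
#' clips by default).
#'
#' @param img `H x W x 3` array.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image_png <- function(img, path) {
  png::writePNG(clip01(as_rgb_image(img)), path)
  invisible(path)
}

#' Checkpoint a named set of planes to a plain binary container
#'
#' Lossless float round trip for intermediate results (channel sets,
#' filling-in surfaces). The format is deliberately simple: a one-line text
#' header per plane (name, rows, cols) followed by little-endian doubles.
#'
#' @param planes named list of numeric matrices.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_planes <- function(planes, path) {
  stopifnot(is.list(planes), length(names(planes)) == length(planes))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(sprintf("chromafill-planes %d", length(planes)), con)
  for (nm in names(planes)) {
    m <- as.matrix(planes[[nm]])
    writeLines(sprintf("%s %d %d", nm, nrow(m), ncol(m)), con)
    writeBin(as.numeric(m), con, size = 8L, endian = "little")
  }
  invisible(path)
}

#' Read a plane container written by [write_planes()]
#'
#' @param path file path.
#' @return named list of numeric matrices.
#' @export
read_planes <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- strsplit(readLines(con, n = 1L), " ", fixed = TRUE)[[1L]]
  if (hdr[1L] != "chromafill-planes") stop("not a plane container", call. = FALSE)
  n <- as.integer(hdr[2L])
  out <- vector("list", n)
  nms <- character(n)
  for (i in seq_len(n)) {
    h <- strsplit(readLines(con, n = 1L), " ", fixed = TRUE)[[1L]]
    nms[i] <- h[1L]
    r <- as.integer(h[2L]); c <- as.integer(h[3L])
    out[[i]] <- matrix(readBin(con, "numeric", r * c, size = 8L, endian = "little"), r, c)
  }
  names(out) <- nms
  out
}

# Evaluate `code` under a temporary RNG seed, restoring the caller's stream.
with_local_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
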