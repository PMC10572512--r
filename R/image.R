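#' Validate and construct an RGB image array
#'
#' An RGB image is represented as an H x W x 3 numeric array with values in
#' \[0, 1\], channel order red/green/blue, rows indexing the vertical (u)
#' coordinate and columns the horizontal (v) coordinate.
#'
#' @param pixels numeric array, either H x W x 3 in \[0,1\] or an integer
#'   0--255 encoding (rescaled to \[0,1\] on construction).
#' @return the validated H x W x 3 array, of class `rgb_image`.
#' @export
rgb_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L)
    stop("expected an H x W x 3 array (three colour channels)")
  if (any(!is.finite(pixels)))
    stop("image contains non-finite values")
  if (max(pixels) > 1) {
    if (max(pixels) > 255 || min(pixels) < 0)
      stop("pixel values must lie in [0,1] (or an integer 0-255 encoding)")
    pixels <- pixels / 255
  }
  if (min(pixels) < 0)
    stop("pixel values must lie in [0,1]")
  if (dim(pixels)[1] < 8L || dim(pixels)[2] < 8L)
    stop("image must be at least 8 x 8")
  structure(pixels, class = "rgb_image")
}

#' Read an RGB image from a PNG file
#'
#' Grayscale and RGBA inputs are expanded/cropped to three channels.
#'
#' @param path file path to a PNG image.
#' @return an `rgb_image` array in \[0,1\].
#' @export
read_image <- function(path) {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2L) px <- array(rep(px, 3L), c(dim(px), 3L))
  if (dim(px)[3] == 4L) px <- px[, , 1:3, drop = FALSE]
  rgb_image(px)
}

#' Write an RGB image (or a binary mask) to a PNG file
#'
#' @param img an H x W x 3 array in \[0,1\], or an H x W logical/0-1 matrix
#'   (written as a single-channel 0/255 mask).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is.logical(img)) img <- img * 1
  img <- unclass(img)
  png::writePNG(pmin(pmax(img, 0), 1), path)
  invisible(path)
}

# Separable Gaussian smoothing with a truncated discrete kernel of half-width
# ceil(3*sigma) and reflective boundary handling. sigma = 0 is the identity.
gaussian_smooth <- function(mat, sigma) {
  if (sigma < 0) stop("sigma must be nonnegative")
  if (sigma == 0) return(mat)
  h <- as.integer(ceiling(3 * sigma))
  k <- exp(-((-h:h)^2) / (2 * sigma^2))
  k <- k / sum(k)
  mat <- smooth_1d(mat, k, h, along_rows = TRUE)
  smooth_1d(mat, k, h, along_rows = FALSE)
}

# Convolve each column (along_rows = TRUE: the filter slides down the rows)
# with kernel k of half-width h, reflecting at the borders. Implemented as a
# weighted sum of shifted copies so the inner work is vectorised.
smooth_1d <- function(mat, k, h, along_rows = TRUE) {
  if (!along_rows) return(t(smooth_1d(t(mat), k, h, along_rows = TRUE)))
  n <- nrow(mat)
  idx <- reflect_index(seq_len(n + 2L * h) - h, n)
  pad <- mat[idx, , drop = FALSE]
  out <- matrix(0, n, ncol(mat))
  for (j in seq_along(k)) {
    out <- out + k[j] * pad[(j - 1L) + seq_len(n), , drop = FALSE]
  }
  out
}

# Map out-of-range indices back into 1..n by reflection about the edges
# (half-sample style: ... 2 1 | 1 2 ... n-1 n | n n-1 ...).
reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  period <- 2L * n
  j <- ((i - 1L) %% period + period) %% period  # 0 .. 2n-1
  ifelse(j < n, j + 1L, period - j)
}
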