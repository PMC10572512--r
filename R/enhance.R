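#' Luminance map of an RGB image
#'
#' Computes a CIELAB-style lightness L* for every pixel: the channels are
#' combined with Rec.709-type weights (0.212, 0.715, 0.072, normalised to sum
#' to one so that pure white maps to relative luminance 1), then passed
#' through the standard cube-root / linear piecewise function and scaled so
#' black maps to 0 and white to 100.
#'
#' @param img an `rgb_image` (H x W x 3 array in \[0,1\]).
#' @return list with `values` (H x W matrix of lightness in \[0,100\]) and
#'   `sigma` (population standard deviation of the lightness values).
#' @seealso [global_sigma()], [texture_residual()]
#' @export
rgb_to_luminance <- function(img) {
  if (!is.array(img) || length(dim(img)) != 3L || dim(img)[3] != 3L)
    stop("expected an H x W x 3 array")
  if (min(img) < 0 || max(img) > 1)
    stop("pixel values must lie in [0,1]")
  w <- c(0.212, 0.715, 0.072)
  w <- w / sum(w)
  y <- w[1] * img[, , 1] + w[2] * img[, , 2] + w[3] * img[, , 3]
  values <- 116 * lab_f(y) - 16
  # guard tiny negative round-off at y == 0
  values[values < 0] <- 0
  list(values = values, sigma = global_sigma(values))
}

# CIELAB piecewise transfer function: cube root above the 0.008856 knee,
# linear 7.787*y + 16/116 below it.
lab_f <- function(y) {
  ifelse(y > 0.008856, y^(1 / 3), 7.787 * y + 16 / 116)
}

lab_f_inv <- function(fy) {
  ifelse(fy > 0.2068930, fy^3, (fy - 16 / 116) / 7.787)
}

#' Global luminance standard deviation
#'
#' The population standard deviation of all pixel values of a luminance map:
#' `sqrt(mean(x^2) - mean(x)^2)`. This single scalar doubles as the spatial
#' standard deviation (in pixels) of the Gaussian filters used downstream.
#'
#' @param L a numeric matrix (or the list returned by [rgb_to_luminance()]).
#' @return a nonnegative scalar; 0 iff the map is constant.
#' @export
global_sigma <- function(L) {
  if (is.list(L)) L <- L$values
  if (length(L) == 0L) stop("empty luminance map")
  v <- mean(L^2) - mean(L)^2
  sqrt(max(v, 0))
}

#' Gaussian texture residual of a luminance map
#'
#' Smooths the map with a Gaussian of standard deviation `sigma` (truncated
#' at half-width `ceil(3*sigma)`, reflective borders) and returns the
#' relative residual `rho = L / phi - L = L * (1 - phi) / phi`, where `phi`
#' is the smoothed map, epsilon-floored at 1e-6 before division.
#'
#' @param L numeric matrix.
#' @param sigma nonnegative smoothing scale in pixels; 0 means identity
#'   smoothing (residual is then `L*(1-L)/L`).
#' @return list with `values` (the residual rho) and `smoothed` (phi).
#' @export
texture_residual <- function(L, sigma) {
  if (is.list(L)) L <- L$values
  if (sigma < 0) stop("sigma must be nonnegative")
  phi <- gaussian_smooth(L, sigma)
  phi_safe <- pmax(phi, 1e-6)
  rho <- L * (1 - phi_safe) / phi_safe
  rho[L == 0] <- 0
  list(values = rho, smoothed = phi)
}

#' Lesion activation mask
#'
#' Pixels whose texture residual exceeds the smoothed luminance are flagged
#' as lesion: `mask = rho > phi`. Dermoscopic lesions are darker than the
#' surrounding skin, and on a \[0,1\]-scaled luminance map the residual
#' dominates the smoothed value exactly in such low-intensity regions.
#'
#' @param rho the list returned by [texture_residual()] (fields `values`
#'   and `smoothed`), or a numeric matrix accompanied by `smoothed`.
#' @param smoothed optional numeric matrix when `rho` is a plain matrix.
#' @return an H x W logical matrix, `TRUE` = lesion.
#' @export
lesion_activation <- function(rho, smoothed = NULL) {
  if (is.list(rho)) {
    smoothed <- rho$smoothed
    rho <- rho$values
  }
  if (is.null(smoothed) || !all(dim(rho) == dim(smoothed)))
    stop("residual and smoothed maps must share shape")
  rho > smoothed
}

#' Retinex colour adjustment
#'
#' Converts the image to CIELAB, divides each of the L, a, b channels by its
#' Gaussian-smoothed version (epsilon-guarded, sign-preserving), min--max
#' rescales each ratio channel back to the channel's original range, converts
#' back to RGB and clips to \[0,1\]. Dividing a channel by its large-scale
#' smoothed version removes slowly varying illumination while retaining
#' reflectance-like local contrast.
#'
#' @param img an `rgb_image`.
#' @param sigma positive smoothing scale in pixels.
#' @param mask optional logical lesion mask; when given, the lesion pixels'
#'   lightness is darkened by the exponent `1/gamma` before the Retinex
#'   division, increasing lesion/skin contrast.
#' @param gamma tone-mapping parameter in (0,1\]; default 0.8.
#' @return an H x W x 3 array in \[0,1\].
#' @export
retinex_adjust <- function(img, sigma, mask = NULL, gamma = 0.8) {
  if (sigma <= 0) stop("sigma must be positive")
  if (gamma <= 0 || gamma > 1) stop("gamma must lie in (0,1]")
  lab <- rgb_to_lab(img)
  if (!is.null(mask)) {
    L <- lab[, , 1]
    L[mask] <- 100 * (pmax(L[mask], 0) / 100)^(1 / gamma)
    lab[, , 1] <- L
  }
  for (i in 1:3) {
    ch <- lab[, , i]
    sm <- gaussian_smooth(ch, sigma)
    denom <- sign(sm) * pmax(abs(sm), 1e-6)
    denom[denom == 0] <- 1e-6
    ratio <- ch / denom
    lo <- min(ch); hi <- max(ch)
    rlo <- min(ratio); rhi <- max(ratio)
    if (rhi - rlo < 1e-12) {
      # constant ratio: channel already free of illumination structure
      next
    }
    lab[, , i] <- lo + (ratio - rlo) / (rhi - rlo) * (hi - lo)
  }
  out <- lab_to_rgb(lab)
  out[] <- pmin(pmax(out, 0), 1)
  out
}

#' Full contrast-enhancement pipeline for one image
#'
#' Composes luminance extraction, global-sigma estimation, Gaussian texture
#' residual, lesion activation and Retinex colour adjustment. The activation
#' stage runs on the linear relative luminance Y in \[0,1\] (not the
#' cube-root-compressed lightness): with a slowly varying smoothed map the
#' inequality `rho > phi` reduces to "local luminance below 0.5", which
#' flags the darker lesion on the brighter skin. The spatial sigma is
#' estimated once from the \[0,100\] lightness map (or overridden via
#' `sigma`).
#'
#' @param img an `rgb_image`.
#' @param sigma `"auto"` (default: population SD of lightness) or a positive
#'   number, the Gaussian scale in pixels for the texture residual.
#' @param gamma lesion tone-mapping parameter in (0,1\]; see
#'   [retinex_adjust()].
#' @param retinex_sigma Gaussian scale for the Retinex illumination
#'   estimate; defaults to `min(H, W) / 3`, the usual single-scale-Retinex
#'   choice. It must exceed the lesion scale, otherwise the division
#'   flattens the lesion itself instead of the illumination field.
#' @return list with `image` (enhanced H x W x 3 array), `mask` (logical
#'   lesion mask), `sigma` (value used), and `contrast` (Michelson
#'   lesion/skin luminance contrast before and after, using the mask).
#' @examples
#' spec <- lesion_image_spec(height = 64, width = 64, seed = 1)
#' im <- make_lesion_image(spec)
#' enh <- enhance(im$image)
#' enh$contrast
#' @export
enhance <- function(img, sigma = "auto", gamma = 0.8, retinex_sigma = NULL) {
  lum <- rgb_to_luminance(img)
  sig <- if (identical(sigma, "auto")) lum$sigma else sigma
  if (!is.numeric(sig) || sig <= 0) sig <- max(lum$sigma, 1)
  if (is.null(retinex_sigma)) retinex_sigma <- min(dim(lum$values)) / 3
  tex <- texture_residual(relative_luminance(img), sig)
  mask <- lesion_activation(tex)
  out <- retinex_adjust(img, retinex_sigma, mask = mask, gamma = gamma)
  c_before <- michelson_contrast(lum$values, mask)
  c_after <- michelson_contrast(rgb_to_luminance(out)$values, mask)
  list(image = out, mask = mask, sigma = sig,
       contrast = c(before = c_before, after = c_after))
}

#' Michelson contrast between two regions of a luminance map
#'
#' `(mean_out - mean_in) / (mean_out + mean_in)` where `in` is the masked
#' (lesion) region; positive when the lesion is darker than the skin.
#'
#' @param L numeric matrix of luminance values.
#' @param mask logical matrix delimiting the lesion region.
#' @return a scalar in \[-1,1\]; `NA` if either region is empty.
#' @export
michelson_contrast <- function(L, mask) {
  if (is.list(L)) L <- L$values
  if (!any(mask) || all(mask)) return(NA_real_)
  m_in <- mean(L[mask]); m_out <- mean(L[!mask])
  if (m_in + m_out == 0) return(0)
  (m_out - m_in) / (m_out + m_in)
}

# Linear relative luminance in [0,1]: the weighted channel sum that feeds
# the lightness transform, without the cube-root compression.
relative_luminance <- function(img) {
  w <- c(0.212, 0.715, 0.072)
  w <- w / sum(w)
  w[1] * img[, , 1] + w[2] * img[, , 2] + w[3] * img[, , 3]
}

# ---- CIELAB conversions -----------------------------------------------------
# Pixel values are treated as linear RGB; XYZ via the sRGB primaries (D65).

.rgb2xyz <- matrix(c(0.4124564, 0.3575761, 0.1804375,
                     0.2126729, 0.7151522, 0.0721750,
                     0.0193339, 0.1191920, 0.9503041),
                   3, 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)
.white <- as.vector(.rgb2xyz %*% c(1, 1, 1))

rgb_to_lab <- function(img) {
  d <- dim(img)
  flat <- matrix(unclass(img), ncol = 3L)
  xyz <- flat %*% t(.rgb2xyz)
  fx <- lab_f(xyz[, 1] / .white[1])
  fy <- lab_f(xyz[, 2] / .white[2])
  fz <- lab_f(xyz[, 3] / .white[3])
  lab <- cbind(116 * fy - 16, 500 * (fx - fy), 200 * (fy - fz))
  array(lab, d)
}

lab_to_rgb <- function(lab) {
  d <- dim(lab)
  flat <- matrix(lab, ncol = 3L)
  fy <- (flat[, 1] + 16) / 116
  fx <- fy + flat[, 2] / 500
  fz <- fy - flat[, 3] / 200
  xyz <- cbind(lab_f_inv(fx) * .white[1],
               lab_f_inv(fy) * .white[2],
               lab_f_inv(fz) * .white[3])
  rgb <- xyz %*% t(.xyz2rgb)
  array(rgb, d)
}
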