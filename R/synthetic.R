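#' Specification for a synthetic dermoscopy-like lesion image
#'
#' Describes a darker, irregular elliptical lesion on a brighter skin
#' background with a multiplicative illumination gradient, dark hair-like
#' strokes and additive Gaussian noise — the artifact classes that make real
#' dermoscopic images hard to enhance and segment.
#'
#' @param height,width image size in pixels (>= 8).
#' @param skin_tone background RGB in \[0,1\].
#' @param lesion_center row/column centre in pixels (default image centre).
#' @param axes ellipse semi-axes (a, b) in pixels.
#' @param rotation ellipse rotation in radians.
#' @param darkening multiplicative lesion darkening factor in (0,1);
#'   the lesion is `darkening` times the local skin colour.
#' @param irregularity amplitude of the sum-of-sinusoids radial border
#'   perturbation (0 = perfect ellipse).
#' @param illumination strength of a multiplicative corner-to-corner
#'   illumination ramp (0 = flat lighting).
#' @param hair_count number of dark hair-like strokes.
#' @param noise_sd additive Gaussian pixel noise standard deviation.
#' @param seed RNG seed; the generator is fully deterministic given the spec.
#' @return list of class `lesion_image_spec`.
#' @export
lesion_image_spec <- function(height = 96L, width = 96L,
                              skin_tone = c(0.85, 0.62, 0.50),
                              lesion_center = NULL,
                              axes = c(height / 5, height / 7),
                              rotation = 0.4,
                              darkening = 0.45,
                              irregularity = 0.15,
                              illumination = 0.25,
                              hair_count = 3L,
                              noise_sd = 0.02,
                              seed = 1L) {
  if (is.null(lesion_center)) lesion_center <- c(height / 2, width / 2)
  spec <- list(height = as.integer(height), width = as.integer(width),
               skin_tone = skin_tone, lesion_center = lesion_center,
               axes = axes, rotation = rotation, darkening = darkening,
               irregularity = irregularity, illumination = illumination,
               hair_count = as.integer(hair_count), noise_sd = noise_sd,
               seed = as.integer(seed))
  if (darkening <= 0 || darkening >= 1) stop("darkening must lie in (0,1)")
  if (noise_sd < 0) stop("noise_sd must be nonnegative")
  max_r <- max(axes) * (1 + irregularity * 1.5)
  if (lesion_center[1] - max_r < 1 || lesion_center[1] + max_r > height ||
      lesion_center[2] - max_r < 1 || lesion_center[2] + max_r > width)
    stop("lesion must lie fully inside the frame")
  class(spec) <- "lesion_image_spec"
  spec
}

#' Generate a synthetic lesion image with ground-truth mask
#'
#' The lesion border follows `r(theta) = r0(theta) * (1 + sum_k a_k
#' sin(k theta + phi_k))` with 3 harmonics; hairs are dark quadratic curves;
#' illumination is a multiplicative linear ramp; noise is additive Gaussian.
#' The returned mask is the exact noise-free lesion region.
#'
#' @param spec a [lesion_image_spec()].
#' @return list with `image` (an `rgb_image`), `mask` (logical ground-truth
#'   lesion region) and the echoed `spec`.
#' @export
make_lesion_image <- function(spec) {
  stopifnot(inherits(spec, "lesion_image_spec"))
  old <- .Random.seed_save()
  set.seed(spec$seed)
  H <- spec$height; W <- spec$width
  u <- matrix(seq_len(H), H, W)           # rows
  v <- matrix(seq_len(W), H, W, byrow = TRUE)

  # elliptical radius field, rotated
  du <- u - spec$lesion_center[1]
  dv <- v - spec$lesion_center[2]
  cr <- cos(spec$rotation); sr <- sin(spec$rotation)
  x <- cr * dv + sr * du
  yy <- -sr * dv + cr * du
  r_ell <- sqrt((x / spec$axes[1])^2 + (yy / spec$axes[2])^2)

  # radial perturbation, 3 harmonics
  amp <- spec$irregularity * c(1, 0.6, 0.4) / sum(c(1, 0.6, 0.4))
  ph <- stats::runif(3, 0, 2 * pi)
  theta <- atan2(yy, x)
  pert <- 1 + amp[1] * sin(theta + ph[1]) + amp[2] * sin(2 * theta + ph[2]) +
    amp[3] * sin(3 * theta + ph[3])
  mask <- r_ell < pert

  img <- array(0, c(H, W, 3))
  for (ch in 1:3) img[, , ch] <- spec$skin_tone[ch]

  # lesion darkening with a slightly soft border
  edge <- pmin(pmax((pert - r_ell) / 0.08, 0), 1)   # 1 inside, 0 outside
  dark <- 1 - (1 - spec$darkening) * edge
  for (ch in 1:3) img[, , ch] <- img[, , ch] * dark

  # multiplicative illumination ramp, corner to corner
  if (spec$illumination > 0) {
    ramp <- 1 + spec$illumination * ((u / H + v / W) / 2 - 0.5) * 2
    for (ch in 1:3) img[, , ch] <- img[, , ch] * ramp
  }

  # hair-like strokes: dark quadratic curves of width ~1px
  if (spec$hair_count > 0) {
    for (h in seq_len(spec$hair_count)) {
      p0 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      p2 <- c(stats::runif(1, 1, H), stats::runif(1, 1, W))
      p1 <- (p0 + p2) / 2 + stats::rnorm(2, 0, min(H, W) / 6)
      tt <- seq(0, 1, length.out = 4L * max(H, W))
      pu <- (1 - tt)^2 * p0[1] + 2 * tt * (1 - tt) * p1[1] + tt^2 * p2[1]
      pv <- (1 - tt)^2 * p0[2] + 2 * tt * (1 - tt) * p1[2] + tt^2 * p2[2]
      iu <- round(pu); iv <- round(pv)
      ok <- iu >= 1 & iu <= H & iv >= 1 & iv <= W
      idx <- cbind(iu[ok], iv[ok])
      shade <- stats::runif(1, 0.15, 0.35)
      for (ch in 1:3) {
        plane <- img[, , ch]
        plane[idx] <- plane[idx] * shade
        img[, , ch] <- plane
      }
    }
  }

  if (spec$noise_sd > 0)
    img <- img + array(stats::rnorm(length(img), 0, spec$noise_sd), dim(img))
  img[] <- pmin(pmax(img, 0), 1)
  .Random.seed_restore(old)
  list(image = rgb_image(img), mask = mask, spec = spec)
}

#' Specification for a planted-structure paired feature dataset
#'
#' Emulates the two per-sample deep-feature matrices of the recognition
#' pipeline: a planted set of class-informative Gaussian columns, pure-noise
#' columns, and redundant column pairs duplicated across the two sources by
#' a strictly monotone transform.
#'
#' @param n_samples number of samples R.
#' @param n_classes number of classes C (labels `0..C-1`).
#' @param d1,d2 per-source feature counts (pipeline-scale defaults are 1024
#'   and 1920; tests use far smaller values).
#' @param k_informative number of class-informative columns, split across
#'   both sources.
#' @param effect_size class-mean separation in within-class SD units.
#' @param n_redundant number of cross-source duplicated (monotone-transform)
#'   column pairs.
#' @param noise_sd within-class standard deviation.
#' @param seed RNG seed.
#' @return list of class `feature_dataset_spec`.
#' @export
feature_dataset_spec <- function(n_samples = 200L, n_classes = 3L,
                                 d1 = 1024L, d2 = 1920L,
                                 k_informative = 20L, effect_size = 2,
                                 n_redundant = 10L, noise_sd = 1,
                                 seed = 1L) {
  stopifnot(n_classes >= 2L, effect_size >= 0,
            k_informative <= d1 + d2, n_redundant <= min(d1, d2),
            n_samples >= 2L * n_classes)
  structure(list(n_samples = as.integer(n_samples),
                 n_classes = as.integer(n_classes),
                 d1 = as.integer(d1), d2 = as.integer(d2),
                 k_informative = as.integer(k_informative),
                 effect_size = effect_size,
                 n_redundant = as.integer(n_redundant),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "feature_dataset_spec")
}

#' Generate a paired feature dataset with planted structure
#'
#' Informative columns get class-conditional means `effect_size * noise_sd *
#' perm(0..C-1)` (a random class ordering per column); redundant pairs copy a
#' source-A column into source B through a strictly monotone transform
#' (`sinh(x/2)`), so their rank correlation is exactly 1; all other columns
#' are independent Gaussian noise.
#'
#' @param spec a [feature_dataset_spec()].
#' @return list with `Fa`, `Fb` (labelled `feature_matrix` objects),
#'   `labels`, `informative` (1-based indices into the concatenated
#'   `cbind(Fa, Fb)` matrix), `redundant_pairs` (two-column matrix of
#'   concatenated-matrix indices) and the echoed `spec`.
#' @export
make_feature_dataset <- function(spec) {
  stopifnot(inherits(spec, "feature_dataset_spec"))
  old <- .Random.seed_save()
  set.seed(spec$seed)
  n <- spec$n_samples; C <- spec$n_classes
  labels <- sort(rep_len(0:(C - 1L), n))
  d1 <- spec$d1; d2 <- spec$d2
  A <- matrix(stats::rnorm(n * d1, 0, spec$noise_sd), n, d1)
  B <- matrix(stats::rnorm(n * d2, 0, spec$noise_sd), n, d2)

  k <- spec$k_informative
  k1 <- min(d1, ceiling(k * d1 / (d1 + d2)))
  # keep informative columns clear of the redundant block at the front of A
  inf_a <- if (k1 > 0) spec$n_redundant + seq_len(k1) else integer(0)
  inf_b <- if (k - k1 > 0) seq_len(k - k1) else integer(0)
  if (length(inf_a) && max(inf_a) > d1) stop("d1 too small for layout")
  sep <- spec$effect_size * spec$noise_sd
  for (j in inf_a) {
    mu <- sep * (sample(C) - 1L)
    A[, j] <- A[, j] + mu[labels + 1L]
  }
  for (j in inf_b) {
    mu <- sep * (sample(C) - 1L)
    B[, j] <- B[, j] + mu[labels + 1L]
  }

  # redundant cross-source pairs: A column j -> B column d2 - n_red + j
  red <- spec$n_redundant
  red_pairs <- NULL
  if (red > 0) {
    src <- seq_len(red)
    dst <- d2 - red + seq_len(red)
    for (i in seq_len(red)) B[, dst[i]] <- sinh(A[, src[i]] / 2)
    red_pairs <- cbind(src, d1 + dst)
  }
  .Random.seed_restore(old)
  list(Fa = feature_matrix(A, labels = labels, source = "A"),
       Fb = feature_matrix(B, labels = labels, source = "B"),
       labels = labels,
       informative = c(inf_a, d1 + inf_b),
       redundant_pairs = red_pairs,
       spec = spec)
}
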