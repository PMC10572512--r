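# Independent straight-line reference implementations used as oracles.
# These deliberately share no code with the package internals.

# CIELAB L* of one RGB triple: weighted relative luminance (weights
# normalised to sum 1) through the cube-root/linear piecewise function.
lstar_ref <- function(r, g, b) {
  w1 <- 0.212 / (0.212 + 0.715 + 0.072)
  w2 <- 0.715 / (0.212 + 0.715 + 0.072)
  w3 <- 0.072 / (0.212 + 0.715 + 0.072)
  y <- w1 * r + w2 * g + w3 * b
  f <- if (y > 0.008856) y^(1 / 3) else 7.787 * y + 16 / 116
  max(116 * f - 16, 0)
}

# Naive O(n k^2) direct 2D Gaussian convolution with the same truncated
# kernel (half-width ceil(3 sigma)) and half-sample reflective borders.
gauss_conv_ref <- function(mat, sigma) {
  h <- ceiling(3 * sigma)
  k1 <- exp(-((-h:h)^2) / (2 * sigma^2))
  k2 <- outer(k1, k1)
  k2 <- k2 / sum(k2)
  n <- nrow(mat); m <- ncol(mat)
  refl <- function(i, n) {
    while (i < 1 || i > n) {
      if (i < 1) i <- 1 - i
      if (i > n) i <- 2 * n + 1 - i
    }
    i
  }
  out <- matrix(0, n, m)
  for (a in seq_len(n)) for (b in seq_len(m)) {
    acc <- 0
    for (da in -h:h) for (db in -h:h) {
      ia <- refl(a + da, n); ib <- refl(b + db, m)
      acc <- acc + k2[da + h + 1, db + h + 1] * mat[ia, ib]
    }
    out[a, b] <- acc
  }
  out
}

# Literal straight-line transcription of the three-phase MPA position
# update and the FADs step, written as explicit per-individual loops.
mpa_phase_ref <- function(prey, elite, t, t_max, F, draws) {
  N <- nrow(prey); d <- ncol(prey)
  AP <- (1 - t / t_max)^(2 * t / t_max)
  P <- prey
  if (t < t_max / 3) {
    for (i in 1:N) {
      V <- draws$RB[i, ] * elite[i, ] - draws$RB[i, ] * prey[i, ]
      P[i, ] <- prey[i, ] + F * draws$R[i, ] * V
    }
  } else if (t < 2 * t_max / 3) {
    for (i in 1:N) {
      if (i <= floor(N / 2)) {
        V <- draws$RL[i, ] * elite[i, ] - draws$RL[i, ] * prey[i, ]
        P[i, ] <- prey[i, ] + F * draws$R[i, ] * V
      } else {
        V <- draws$RB[i, ] * (draws$RB[i, ] * elite[i, ] - prey[i, ])
        P[i, ] <- prey[i, ] + F * AP * V
      }
    }
  } else {
    for (i in 1:N) {
      V <- draws$RL[i, ] * (draws$RL[i, ] * elite[i, ] - prey[i, ])
      P[i, ] <- elite[i, ] + F * AP * V
    }
  }
  pmin(pmax(P, 0), 1)
}

mpa_fads_ref <- function(prey, t, t_max, fads_rate, draws) {
  N <- nrow(prey); d <- ncol(prey)
  AP <- (1 - t / t_max)^(2 * t / t_max)
  P <- prey
  for (i in 1:N) {
    r <- draws$r[i]
    if (r < fads_rate) {
      P[i, ] <- prey[i, ] + AP * (0 + draws$R[i, ] * (1 - 0)) * draws$B[i, ]
    } else {
      r1 <- draws$swap[i, 1]; r2 <- draws$swap[i, 2]
      P[i, ] <- prey[i, ] + (fads_rate * (1 - r) + r) *
        (prey[r1, ] - prey[r2, ])
    }
  }
  pmin(pmax(P, 0), 1)
}

# Shannon entropy (natural log), for the Renyi continuity check.
shannon_ref <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Random probability simplex.
rand_simplex <- function(d) {
  x <- stats::rexp(d)
  x / sum(x)
}
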