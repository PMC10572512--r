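#' Configuration for Marine-Predator-Algorithm feature selection
#'
#' @param population_size number of candidate solutions N (default 20).
#' @param iterations maximum iteration count t_max (default 200).
#' @param step_constant fixed step multiplier F in (0,1\] (default 0.4).
#' @param fads_rate probability of the FADs (fish-aggregating-devices)
#'   perturbation branch, in \[0,1\] (default 0.4).
#' @param levy_beta stability index of the Levy flight, in (0,2) (default 1.5).
#' @param renyi_alpha Renyi entropy order, > 1 (default 2).
#' @param bounds length-2 vector of position bounds (default `c(0,1)`).
#' @param binarize_threshold position value above which a feature counts as
#'   selected (default 0.5).
#' @param knn_k neighbours used by the k-NN wrapper fitness (default 5).
#' @param seed master seed for the whole run.
#' @return list of class `mpa_config`.
#' @export
mpa_config <- function(population_size = 20L, iterations = 200L,
                       step_constant = 0.4, fads_rate = 0.4,
                       levy_beta = 1.5, renyi_alpha = 2,
                       bounds = c(0, 1), binarize_threshold = 0.5,
                       knn_k = 5L, seed = 1L) {
  stopifnot(population_size >= 4L, iterations >= 3L,
            step_constant > 0, step_constant <= 1,
            fads_rate >= 0, fads_rate <= 1,
            levy_beta > 0, levy_beta < 2,
            renyi_alpha > 1,
            length(bounds) == 2L, bounds[1] < bounds[2])
  structure(list(population_size = as.integer(population_size),
                 iterations = as.integer(iterations),
                 step_constant = step_constant, fads_rate = fads_rate,
                 levy_beta = levy_beta, renyi_alpha = renyi_alpha,
                 bounds = bounds, binarize_threshold = binarize_threshold,
                 knn_k = as.integer(knn_k), seed = as.integer(seed)),
            class = "mpa_config")
}

#' Initial predator/prey population
#'
#' Positions are uniform on the search box: `x = A_min + r * (A_max - A_min)`
#' with r ~ U(0,1) entry-wise. The Elite matrix replicates the fittest
#' individual; when no fitness function is supplied the first individual
#' seeds the Elite until the first evaluation.
#'
#' @param d number of dimensions (features), >= 2.
#' @param config an [mpa_config()].
#' @param fitness_fun optional function(position vector) -> fitness in
#'   \[0,1\] (lower is better), used to pick the initial elite.
#' @return list of class `predator_state`: `prey` (N x d), `elite` (N x d,
#'   identical rows), `fitness` (length N), `best_fitness`, `best_position`,
#'   `t` (iteration counter, 0).
#' @export
init_population <- function(d, config, fitness_fun = NULL) {
  if (d < 2L) stop("need at least 2 dimensions")
  N <- config$population_size
  lo <- config$bounds[1]; hi <- config$bounds[2]
  prey <- matrix(lo + stats::runif(N * d) * (hi - lo), N, d)
  fitness <- rep(NA_real_, N)
  if (!is.null(fitness_fun)) fitness <- apply(prey, 1L, fitness_fun)
  best <- if (all(is.na(fitness))) 1L else which.min(fitness)
  state <- list(prey = prey,
                elite = matrix(prey[best, ], N, d, byrow = TRUE),
                fitness = fitness,
                best_fitness = if (is.na(fitness[best])) Inf else fitness[best],
                best_position = prey[best, ],
                t = 0L)
  class(state) <- "predator_state"
  state
}

#' Brownian step vector
#'
#' Standard normal draws, the Brownian foraging move of the high- and
#' unit-velocity phases.
#'
#' @param d length of the vector.
#' @return numeric vector of N(0,1) draws.
#' @export
brownian_vector <- function(d) stats::rnorm(d)

#' Levy step vector (Mantegna's algorithm)
#'
#' Heavy-tailed stable draws with index `beta`: `u / |v|^(1/beta)` with
#' u ~ N(0, sigma_u^2), v ~ N(0,1) and sigma_u chosen by Mantegna's formula.
#'
#' @param d length of the vector.
#' @param beta stability index in (0,2), default 1.5.
#' @return numeric vector of heavy-tailed draws.
#' @export
levy_vector <- function(d, beta = 1.5) {
  sigma_u <- (gamma(1 + beta) * sin(pi * beta / 2) /
                (gamma((1 + beta) / 2) * beta * 2^((beta - 1) / 2)))^(1 / beta)
  u <- stats::rnorm(d, 0, sigma_u)
  v <- stats::rnorm(d)
  u / abs(v)^(1 / beta)
}

#' Adaptive step-size parameter
#'
#' `AP(t) = (1 - t/t_max)^(2 t / t_max)`: 1 at the first iteration, 0 at the
#' last, 0.5 at mid-run; it shrinks the Brownian/Levy steps as the search
#' turns from exploration to exploitation.
#'
#' @param t current iteration, `0 <= t <= t_max`.
#' @param t_max maximum iteration count.
#' @return a scalar in \[0,1\].
#' @export
adaptive_AP <- function(t, t_max) {
  if (t < 0 || t > t_max) stop("t must lie in [0, t_max]")
  (1 - t / t_max)^(2 * t / t_max)
}

# Draw the full set of random quantities one phase update consumes, so the
# update itself is a pure function of (state, draws) and can be checked
# against a straight-line transcription with pinned draws.
draw_phase_randoms <- function(N, d, beta) {
  list(RB  = matrix(stats::rnorm(N * d), N, d),
       RL  = matrix(levy_vector(N * d, beta), N, d),
       R   = matrix(stats::runif(N * d), N, d))
}

#' One MPA position update (three velocity-ratio phases)
#'
#' Applies the iteration-indexed movement rule and clips to bounds:
#' \itemize{
#' \item phase 1 (`t < t_max/3`, high velocity ratio): Brownian search,
#'   `V = RB*Elite - RB*P`, `P <- P + F * R * V`;
#' \item phase 2 (`t_max/3 <= t < 2 t_max/3`, unit ratio): the first half of
#'   the population takes Levy steps (`V = RL*Elite - RL*P`,
#'   `P <- P + F * R * V`), the second half Brownian steps around the Elite
#'   scaled by the adaptive parameter (`V = RB*(RB*Elite - P)`,
#'   `P <- P + F * AP * V`);
#' \item phase 3 (`t >= 2 t_max/3`, low ratio): Levy exploitation around the
#'   Elite, `V = RL*(RL*Elite - P)`, `P <- Elite + F * AP * V`.
#' }
#'
#' @param state a `predator_state`.
#' @param config an [mpa_config()].
#' @param draws optional list of pinned random matrices (`RB`, `RL`, `R`,
#'   each N x d); drawn internally when `NULL`.
#' @return the updated `predator_state` (prey moved, counter untouched).
#' @export
phase_update <- function(state, config, draws = NULL) {
  N <- nrow(state$prey); d <- ncol(state$prey)
  t <- state$t; t_max <- config$iterations
  F <- config$step_constant
  if (is.null(draws)) draws <- draw_phase_randoms(N, d, config$levy_beta)
  P <- state$prey; E <- state$elite
  AP <- adaptive_AP(t, t_max)
  if (t < t_max / 3) {
    V <- draws$RB * E - draws$RB * P
    P <- P + F * draws$R * V
  } else if (t < 2 * t_max / 3) {
    half <- seq_len(floor(N / 2))
    rest <- setdiff(seq_len(N), half)
    V1 <- draws$RL[half, , drop = FALSE] * E[half, , drop = FALSE] -
      draws$RL[half, , drop = FALSE] * P[half, , drop = FALSE]
    P[half, ] <- P[half, , drop = FALSE] +
      F * draws$R[half, , drop = FALSE] * V1
    V2 <- draws$RB[rest, , drop = FALSE] *
      (draws$RB[rest, , drop = FALSE] * E[rest, , drop = FALSE] -
         P[rest, , drop = FALSE])
    P[rest, ] <- P[rest, , drop = FALSE] + F * AP * V2
  } else {
    V <- draws$RL * (draws$RL * E - P)
    P <- E + F * AP * V
  }
  state$prey <- clip_bounds(P, config$bounds)
  state
}

# Random quantities consumed by one FADs step, pinnable like the phase draws.
draw_fads_randoms <- function(N, d, fads_rate) {
  list(r = stats::runif(N),
       R = matrix(stats::runif(N * d), N, d),
       B = matrix(as.numeric(stats::runif(N * d) < fads_rate), N, d),
       swap = t(vapply(seq_len(N),
                       function(i) sample(setdiff(seq_len(N), i), 2L),
                       integer(2L))))
}

#' FADs perturbation step
#'
#' Fish-aggregating-devices effect: with per-individual probability draw r,
#' either a bounded random jump masked by a binary vector
#' (`P <- P + AP * (x_min + R*(x_max - x_min)) * B` when `r < fads_rate`) or
#' a swap-style move along the line between two distinct random individuals
#' (`P <- P + (fads_rate*(1-r) + r) * (P_r1 - P_r2)` otherwise). Positions
#' are clipped to bounds.
#'
#' @inheritParams phase_update
#' @param draws optional pinned list (`r` length N, `R` and `B` N x d,
#'   `swap` N x 2 indices).
#' @return the updated `predator_state`.
#' @export
fads_step <- function(state, config, draws = NULL) {
  N <- nrow(state$prey); d <- ncol(state$prey)
  lo <- config$bounds[1]; hi <- config$bounds[2]
  if (is.null(draws)) draws <- draw_fads_randoms(N, d, config$fads_rate)
  AP <- adaptive_AP(state$t, config$iterations)
  P <- state$prey
  P_old <- P
  for (i in seq_len(N)) {
    if (draws$r[i] < config$fads_rate) {
      jump <- AP * (lo + draws$R[i, ] * (hi - lo)) * draws$B[i, ]
      P[i, ] <- P[i, ] + jump
    } else if (N >= 3L) {
      r1 <- draws$swap[i, 1]; r2 <- draws$swap[i, 2]
      P[i, ] <- P[i, ] + (config$fads_rate * (1 - draws$r[i]) + draws$r[i]) *
        (P_old[r1, ] - P_old[r2, ])
    }
  }
  state$prey <- clip_bounds(P, config$bounds)
  state
}

clip_bounds <- function(P, bounds) {
  P[P < bounds[1]] <- bounds[1]
  P[P > bounds[2]] <- bounds[2]
  P
}

#' Renyi entropy of a probability vector
#'
#' `Ent_alpha(p) = log(sum(p^alpha)) / (1 - alpha)` with the natural log.
#' Approaches Shannon entropy as alpha -> 1; equals `log(d)` for the uniform
#' distribution and 0 for a point mass, for any alpha.
#'
#' @param p probability vector (entries >= 0, summing to 1 within 1e-9).
#' @param alpha entropy order, > 1.
#' @return a nonnegative scalar.
#' @export
renyi_entropy <- function(p, alpha) {
  if (alpha <= 1) stop("alpha must exceed 1")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9)
    stop("p must be a probability vector summing to 1")
  log(sum(p^alpha)) / (1 - alpha)
}

#' Entropy gate over a predator population
#'
#' Each individual's position is normalised to a simplex and its Renyi
#' entropy divided by `log(d)` (so 1 = perfectly spread, 0 = concentrated on
#' one feature). Individuals at or above the population median pass and are
#' re-evaluated this iteration; the rest retain their previous fitness.
#' All-zero rows count as uniform. Ties at the median pass.
#'
#' @param state a `predator_state`.
#' @param config an [mpa_config()].
#' @return logical vector of length N.
#' @export
entropy_gate <- function(state, config) {
  d <- ncol(state$prey)
  ent <- apply(state$prey, 1L, function(x) {
    s <- sum(x)
    p <- if (s <= 0) rep(1 / d, d) else x / s
    renyi_entropy(p, config$renyi_alpha)
  }) / log(d)
  ent >= stats::median(ent)
}

#' k-NN wrapper fitness of a feature mask
#'
#' The fitness of a candidate feature subset is the misclassification rate
#' of a k-nearest-neighbour classifier (default k = 5) under stratified
#' 2-fold cross-validation on the masked columns; lower is better. An empty
#' mask is penalised with fitness 1. The fold assignment is supplied by the
#' caller so fitness is a deterministic function of the mask.
#'
#' @param mask logical vector over columns of `X`.
#' @param X numeric sample-by-feature matrix.
#' @param y integer class labels.
#' @param folds integer vector (1/2) assigning each sample to a fold; built
#'   with [make_cv_folds()] when `NULL` (seeded by `seed`).
#' @param k neighbours (default 5).
#' @param seed seed for the default fold assignment.
#' @return misclassification rate in \[0,1\].
#' @export
mask_fitness <- function(mask, X, y, folds = NULL, k = 5L, seed = 1L) {
  if (!any(mask)) return(1)
  if (min(table(y)) < 2L) stop("need at least 2 samples per class")
  if (is.null(folds)) folds <- make_cv_folds(y, 2L, seed)
  Xm <- X[, mask, drop = FALSE]
  err <- 0; n <- 0
  for (f in 1:2) {
    tr <- folds != f; te <- folds == f
    pred <- knn_predict(Xm[tr, , drop = FALSE], y[tr],
                        Xm[te, , drop = FALSE], k = k)
    err <- err + sum(pred != y[te]); n <- n + sum(te)
  }
  err / n
}

#' Stratified cross-validation fold assignment
#'
#' @param y integer class labels.
#' @param nfold number of folds.
#' @param seed seed for the shuffle within each class.
#' @return integer vector of fold ids in `1..nfold`.
#' @export
make_cv_folds <- function(y, nfold = 2L, seed = 1L) {
  folds <- integer(length(y))
  old <- .Random.seed_save()
  set.seed(seed)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(nfold), length(idx)))
  }
  .Random.seed_restore(old)
  folds
}

# Fast k-NN prediction: BLAS distance matrix + majority vote.
# Supports Minkowski p (2 = Euclidean, 3 = cubic) and optional inverse
# distance weighting.
knn_predict <- function(Xtr, ytr, Xte, k = 5L, p = 2, weighted = FALSE) {
  k <- min(k, nrow(Xtr))
  if (p == 2) {
    d2 <- outer(rowSums(Xte^2), rowSums(Xtr^2), "+") -
      2 * tcrossprod(Xte, Xtr)
    D <- sqrt(pmax(d2, 0))
  } else {
    D <- matrix(0, nrow(Xte), nrow(Xtr))
    for (j in seq_len(ncol(Xtr)))
      D <- D + abs(outer(Xte[, j], Xtr[, j], "-"))^p
    D <- D^(1 / p)
  }
  classes <- sort(unique(ytr))
  pred <- integer(nrow(Xte))
  for (i in seq_len(nrow(Xte))) {
    nn <- order(D[i, ])[seq_len(k)]
    if (weighted) {
      w <- 1 / pmax(D[i, nn], 1e-9)
      votes <- tapply(w, factor(ytr[nn], levels = classes), sum)
      votes[is.na(votes)] <- 0
    } else {
      votes <- table(factor(ytr[nn], levels = classes))
    }
    pred[i] <- classes[which.max(votes)]
  }
  pred
}

#' Marine-Predator-Algorithm feature selection
#'
#' Runs the full wrapper loop: uniform initialisation, then per iteration an
#' entropy gate (only sufficiently spread candidates are re-evaluated),
#' k-NN fitness of the binarised positions, elite update, the three-phase
#' position update and the FADs perturbation. The best position ever seen is
#' binarised at `binarize_threshold` into the final mask.
#'
#' @param X a `feature_matrix` with labels, or a plain numeric matrix.
#' @param y integer labels (ignored when `X` carries labels).
#' @param config an [mpa_config()].
#' @return list of class `mpa_selection`: `mask` (logical), `selected_indices`
#'   (sorted, 1-based), `fitness_history` (length t_max, best-so-far, hence
#'   non-increasing), `final_fitness`, `config`.
#' @examples
#' spec <- feature_dataset_spec(n_samples = 60, d1 = 10, d2 = 10,
#'                              k_informative = 4, seed = 7)
#' ds <- make_feature_dataset(spec)
#' res <- select_features(ds$Fa, config = mpa_config(iterations = 20, seed = 7))
#' res$selected_indices
#' @export
select_features <- function(X, y = NULL, config = mpa_config()) {
  if (inherits(X, "feature_matrix")) {
    if (is.null(y)) y <- X$labels
    X <- X$values
  }
  if (is.null(y)) stop("labels are required for wrapper selection")
  if (nrow(X) < 10L) stop("need at least 10 samples")
  d <- ncol(X)
  if (d < 2L) stop("need at least 2 features")
  if (length(unique(y)) < 2L) stop("need at least 2 classes")

  set.seed(config$seed)
  folds <- make_cv_folds(y, 2L, config$seed)
  cache <- new.env(parent = emptyenv())
  fit_one <- function(pos) {
    mask <- pos >= config$binarize_threshold
    if (!any(mask)) return(1)
    key <- rawToChar(as.raw(44L + mask))
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    val <- mask_fitness(mask, X, y, folds = folds, k = config$knn_k)
    cache[[key]] <- val
    val
  }

  state <- init_population(d, config, fitness_fun = fit_one)
  history <- numeric(config$iterations)
  for (t in seq_len(config$iterations)) {
    state$t <- t - 1L
    pass <- entropy_gate(state, config)
    new_fit <- state$fitness
    new_fit[pass] <- apply(state$prey[pass, , drop = FALSE], 1L, fit_one)
    state$fitness <- new_fit
    b <- which.min(state$fitness)
    if (state$fitness[b] < state$best_fitness) {
      state$best_fitness <- state$fitness[b]
      state$best_position <- state$prey[b, ]
    }
    state$elite <- matrix(state$best_position, nrow(state$prey), d,
                          byrow = TRUE)
    history[t] <- state$best_fitness
    state <- phase_update(state, config)
    state <- fads_step(state, config)
  }
  mask <- state$best_position >= config$binarize_threshold
  if (!any(mask)) mask[which.max(state$best_position)] <- TRUE
  structure(list(mask = mask,
                 selected_indices = which(mask),
                 fitness_history = history,
                 final_fitness = state$best_fitness,
                 config = config),
            class = "mpa_selection")
}

#' @export
print.mpa_selection <- function(x, ...) {
  cat(sprintf(
    "<mpa_selection: %d of %d features, final k-NN CV error %.4f>\n",
    sum(x$mask), length(x$mask), x$final_fitness))
  invisible(x)
}

#' @export
summary.mpa_selection <- function(object, ...) {
  cat("Marine Predator Algorithm feature selection\n")
  cat(sprintf("  features: %d selected of %d\n",
              sum(object$mask), length(object$mask)))
  cat(sprintf("  final fitness (k-NN CV error): %.4f\n",
              object$final_fitness))
  cat(sprintf("  iterations: %d, population: %d, seed: %d\n",
              object$config$iterations, object$config$population_size,
              object$config$seed))
  invisible(object)
}

#' Plot the fitness trajectory of a selection run
#'
#' @param x an `mpa_selection`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.mpa_selection <- function(x, ...) {
  graphics::plot(seq_along(x$fitness_history), x$fitness_history,
                 type = "s", xlab = "iteration",
                 ylab = "best k-NN CV error", ...)
}
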