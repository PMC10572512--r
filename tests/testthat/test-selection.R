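tiny_planted <- function(seed = 11, n = 60, d1 = 4, d2 = 4, k = 3,
                         effect = 1.5, classes = 2) {
  ds <- make_feature_dataset(feature_dataset_spec(
    n_samples = n, n_classes = classes, d1 = d1, d2 = d2,
    k_informative = k, n_redundant = 0, effect_size = effect, seed = seed))
  list(X = cbind(ds$Fa$values, ds$Fb$values), y = ds$labels,
       informative = ds$informative)
}

test_that("population initialisation is uniform, bounded and seed-reproducible", {
  cfg <- mpa_config(population_size = 10L, iterations = 10L, seed = 3L)
  set.seed(3); s1 <- init_population(5L, cfg)
  set.seed(3); s2 <- init_population(5L, cfg)
  expect_identical(s1$prey, s2$prey)
  expect_true(all(s1$prey >= 0 & s1$prey <= 1))
  expect_true(all(apply(s1$elite, 2L, function(col) length(unique(col)) == 1L)))
  expect_error(init_population(1L, cfg), "2 dimensions")

  cfg2 <- mpa_config(population_size = 10000L, iterations = 10L, seed = 4L)
  set.seed(4)
  big <- init_population(2L, cfg2)
  expect_lt(abs(mean(big$prey) - 0.5), 0.02)
})

test_that("Brownian draws are standard normal and Levy draws heavy-tailed", {
  set.seed(5)
  b <- brownian_vector(1e5)
  expect_lt(abs(mean(b)), 0.02)
  expect_lt(abs(var(b) - 1), 0.03)
  l <- levy_vector(1e5, beta = 1.5)
  expect_gt(mean(abs(l) > 3), 2 * pnorm(-3))
})

test_that("adaptive parameter follows its closed-form schedule", {
  expect_identical(adaptive_AP(0, 200), 1)
  expect_identical(adaptive_AP(200, 200), 0)
  expect_equal(adaptive_AP(100, 200), 0.5)
  expect_error(adaptive_AP(201, 200), "t_max")
})

test_that("phase update matches hand computation and the literal transcription", {
  # pinned single-dimension example: V = 0.5*0.8 - 0.5*0.2 = 0.3,
  # new prey = 0.2 + 0.4*1.0*0.3 = 0.32
  cfg <- mpa_config(population_size = 4L, iterations = 30L, seed = 1L)
  st <- list(prey = matrix(0.2, 4, 2), elite = matrix(0.8, 4, 2),
             fitness = rep(0.5, 4), best_fitness = 0.5,
             best_position = rep(0.8, 2), t = 0L)
  class(st) <- "predator_state"
  draws <- list(RB = matrix(0.5, 4, 2), RL = matrix(0.1, 4, 2),
                R = matrix(1.0, 4, 2))
  up <- phase_update(st, cfg, draws = draws)
  expect_equal(up$prey, matrix(0.32, 4, 2), tolerance = 1e-12)

  # all three phases against the straight-line per-individual transcription
  set.seed(9)
  for (t in c(0L, 5L, 12L, 20L, 25L)) {
    st$t <- t
    st$prey <- matrix(runif(8), 4, 2)
    st$elite <- matrix(rep(runif(2), each = 4), 4, 2)
    dr <- list(RB = matrix(rnorm(8), 4, 2),
               RL = matrix(levy_vector(8), 4, 2),
               R = matrix(runif(8), 4, 2))
    got <- phase_update(st, cfg, draws = dr)$prey
    ref <- mpa_phase_ref(st$prey, st$elite, t, 30L, 0.4, dr)
    expect_equal(got, ref, tolerance = 1e-12)
    expect_true(all(got >= 0 & got <= 1))
  }
})

test_that("FADs step matches the transcription and honours its branches", {
  cfg <- mpa_config(population_size = 5L, iterations = 20L, seed = 1L)
  st <- list(prey = matrix(runif(15), 5, 3), elite = matrix(0.5, 5, 3),
             fitness = rep(0.5, 5), best_fitness = 0.5,
             best_position = rep(0.5, 3), t = 4L)
  class(st) <- "predator_state"
  set.seed(10)
  dr <- list(r = runif(5), R = matrix(runif(15), 5, 3),
             B = matrix(rbinom(15, 1, 0.4), 5, 3),
             swap = t(sapply(1:5, function(i) sample(setdiff(1:5, i), 2))))
  got <- fads_step(st, cfg, draws = dr)$prey
  ref <- mpa_fads_ref(st$prey, 4L, 20L, 0.4, dr)
  expect_equal(got, ref, tolerance = 1e-12)
  expect_true(all(got >= 0 & got <= 1))

  # all-zero binary vector and r < rate leaves the individual unchanged
  dr0 <- dr
  dr0$r[] <- 0.1
  dr0$B[] <- 0
  same <- fads_step(st, cfg, draws = dr0)$prey
  expect_equal(same, st$prey, tolerance = 1e-12)
})

test_that("Renyi entropy hits its closed forms and the Shannon limit", {
  d <- 7L
  expect_equal(renyi_entropy(rep(1 / d, d), 2), log(d), tolerance = 1e-12)
  expect_equal(renyi_entropy(rep(1 / d, d), 5), log(d), tolerance = 1e-12)
  expect_equal(renyi_entropy(c(1, 0, 0), 2), 0, tolerance = 1e-12)
  expect_equal(renyi_entropy(c(0.5, 0.25, 0.25), 2), -log(0.375),
               tolerance = 1e-12)
  expect_error(renyi_entropy(c(0.5, 0.4), 2), "probability")
  expect_error(renyi_entropy(c(0.5, 0.5), 1), "alpha")
  set.seed(12)
  for (i in 1:30) {
    p <- rand_simplex(sample(3:20, 1))
    expect_equal(renyi_entropy(p, 1.001), shannon_ref(p), tolerance = 1e-3)
  }
})

test_that("entropy gate passes spread candidates and fails concentrated ones", {
  cfg <- mpa_config(population_size = 6L, iterations = 10L, seed = 1L)
  prey <- matrix(1, 6, 8)              # uniform rows
  prey[3, ] <- c(1, rep(1e-6, 7))      # one concentrated row
  st <- list(prey = prey, elite = prey, fitness = rep(0.5, 6),
             best_fitness = 0.5, best_position = prey[1, ], t = 0L)
  class(st) <- "predator_state"
  g <- entropy_gate(st, cfg)
  expect_type(g, "logical")
  expect_length(g, 6L)
  expect_false(g[3])
  expect_true(all(g[-3]))

  # identical individuals all tie at the median and all pass
  st$prey <- matrix(0.3, 6, 8)
  expect_true(all(entropy_gate(st, cfg)))
})

test_that("mask fitness is a bounded seeded error rate with empty-mask penalty", {
  tp <- tiny_planted(effect = 3)
  folds <- make_cv_folds(tp$y, 2L, 1L)
  expect_identical(mask_fitness(rep(FALSE, 8), tp$X, tp$y, folds), 1)
  inf_mask <- seq_len(ncol(tp$X)) %in% tp$informative
  f_inf <- mask_fitness(inf_mask, tp$X, tp$y, folds)
  expect_lt(f_inf, 0.05)
  expect_gte(f_inf, 0)
  # deterministic given folds
  expect_identical(f_inf, mask_fitness(inf_mask, tp$X, tp$y, folds))
  # a singleton class cannot be split
  sub <- c(1L, 2L, 31L)
  expect_error(mask_fitness(inf_mask, tp$X[sub, ], tp$y[sub]), "2 samples")
})

test_that("full selection run is monotone, bounded, reproducible", {
  tp <- tiny_planted(seed = 31)
  fm <- feature_matrix(tp$X, labels = tp$y)
  cfg <- mpa_config(iterations = 25L, seed = 7L)
  res <- select_features(fm, config = cfg)
  expect_s3_class(res, "mpa_selection")
  expect_true(all(diff(res$fitness_history) <= 0))
  expect_gte(length(res$selected_indices), 1L)
  expect_identical(res$selected_indices, which(res$mask))
  expect_length(res$fitness_history, 25L)

  res2 <- select_features(fm, config = cfg)
  expect_identical(res$mask, res2$mask)
  expect_identical(res$fitness_history, res2$fitness_history)
})

test_that("selection approaches the exhaustive-subset optimum on a tiny instance", {
  # d = 8, enumerate all 255 nonempty subsets with the same CV folds
  hits <- 0L
  for (s in 1:3) {
    tp <- tiny_planted(seed = 100 + s)
    cfg <- mpa_config(iterations = 40L, seed = s)
    res <- select_features(feature_matrix(tp$X, labels = tp$y), config = cfg)
    folds <- make_cv_folds(tp$y, 2L, s)
    best <- 1
    for (m in 1:255) {
      mask <- as.logical(bitwAnd(m, 2^(0:7)))
      best <- min(best, mask_fitness(mask, tp$X, tp$y, folds))
    }
    if (res$final_fitness <= best + 0.02) hits <- hits + 1L
  }
  expect_gte(hits, 2L)
})
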