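test_that("forward pass follows the threshold-subtracting layer equations", {
  z <- mlp_new(3, init = "zero")
  expect_equal(mlp_forward(z, c(0.2, 0.4, 0.6, 0.8)), 0)

  m <- mlp_new(1, init = "zero")
  m$W2 <- matrix(2, 1, 1)        # hidden = sigmoid(0) = 0.5, y = 2 * 0.5
  expect_equal(mlp_forward(m, rep(0.3, 4)), 1.0)

  # permuting hidden units together with their weights leaves y unchanged
  m2 <- mlp_new(4, init = "uniform", seed = 7)
  x <- runif(4)
  p <- c(3, 1, 4, 2)
  mp <- m2
  mp$W1 <- m2$W1[p, ]; mp$th1 <- m2$th1[p]; mp$W2 <- m2$W2[, p, drop = FALSE]
  expect_equal(mlp_forward(mp, x), mlp_forward(m2, x), tolerance = 1e-12)

  expect_error(mlp_forward(m2, c(1, 2)), "dimension")
})

test_that("mse matches its definition and a one-line oracle", {
  expect_equal(mse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(mse(c(1, -1), c(0, 0)), 1.0)
  expect_equal(mse(3, 0, weights = 2), 18.0)
  expect_error(mse(1:3, 1:2), "differ")
  for (s in 1:100) {
    v <- withr::with_seed(s, list(p = rnorm(7), a = rnorm(7), w = runif(7)))
    expect_equal(mse(v$p, v$a, v$w), sum(v$w * (v$p - v$a)^2) / 7,
                 tolerance = 1e-12)
  }
})

test_that("genome encode/decode round-trips random models", {
  for (s in 1:20) {
    H <- withr::with_seed(s, sample(2:8, 1))
    m <- mlp_new(H, init = "uniform", seed = s)
    m2 <- genome_decode(genome_encode(m), H)
    expect_equal(m2$W1, m$W1)
    expect_equal(m2$W2, m$W2)
    expect_equal(m2$th1, m$th1)
    expect_equal(m2$th2, m$th2)
  }
  expect_error(genome_decode(rep(0, 10), hidden = 6), "decode")
})

test_that("fitness is the guarded reciprocal of the half mean squared error", {
  X <- matrix(runif(8), 2, 4)
  m <- mlp_new(2, init = "uniform", seed = 1)
  y_perfect <- mlp_forward(m, X)
  g <- genome_encode(m)
  expect_equal(ga_fitness(g, X, y_perfect, 2), 1e12)       # zero-error cap
  # N = 2 with unit errors: E = (1 + 1) / 4 = 0.5, f = 2
  expect_equal(ga_fitness(g, X, y_perfect + c(1, -1), 2), 2, tolerance = 1e-6)
  # strictly decreasing in the error
  f1 <- ga_fitness(g, X, y_perfect + 0.1, 2)
  f2 <- ga_fitness(g, X, y_perfect + 0.2, 2)
  expect_gt(f1, f2)
})

test_that("roulette selection is fitness-proportionate", {
  freq <- withr::with_seed(11, {
    draws <- replicate(20000, roulette_select(c(3, 1)))
    tabulate(draws, 2) / 20000
  })
  expect_equal(freq, c(0.75, 0.25), tolerance = 0.02)

  freq4 <- withr::with_seed(12, {
    draws <- replicate(20000, roulette_select(c(1, 1, 1, 1)))
    tabulate(draws, 4) / 20000
  })
  expect_equal(freq4, rep(0.25, 4), tolerance = 0.02)

  expect_error(roulette_select(c(0, 0)), "degenerate")
  expect_error(roulette_select(c(-1, 2)), "negative")
})

test_that("blend crossover degenerates exactly at s = 0, 0.5 and 1", {
  a <- c(0.2, -0.5, 0.9); b <- c(-0.1, 0.4, 0.0)
  expect_equal(crossover(a, b, s = 1), list(a, b))
  expect_equal(crossover(a, b, s = 0), list(b, a))
  expect_equal(crossover(a, b, s = 0.5), list((a + b) / 2, (a + b) / 2))
  expect_error(crossover(a, b[1:2]), "length")
  # pe = 0 always copies the parents
  withr::with_seed(1, expect_equal(crossover(a, b, pe = 0), list(a, b)))
})

test_that("non-uniform mutation anneals to zero and respects bounds", {
  g <- c(-0.5, 0, 0.7)
  # final generation: annealing factor is zero regardless of draws
  expect_equal(mutate(g, pm = 1, r = 50, r_max = 50, s1 = 0.9, r2 = 0.9), g)
  # a gene at the upper bound moving up stays put
  expect_equal(mutate(1, pm = 1, r = 1, r_max = 10, s1 = 0.8, r2 = 0.9), 1)
  # bound preservation under many random draws
  for (s in 1:20) {
    out <- withr::with_seed(s, mutate(runif(30, -1, 1), pm = 1,
                                      r = sample(1:9, 1), r_max = 10))
    expect_true(all(out >= -1 & out <= 1))
  }
  expect_error(mutate(c(5, 0), pm = 1, r = 1, r_max = 2), "outside")
})

test_that("the GA keeps its best-fitness trace monotone and genes in bounds", {
  tbl <- crab_table(seed = 3)
  X <- cbind(as.numeric(tbl$gender == "male"), tbl$weight_g,
             tbl$fatness_pct, tbl$shell_gray)
  Xs <- apply_scaling(X, fit_scaling(X))
  y <- grade_targets(3)[tbl$grade]
  cfg <- ga_config(pop_size = 20, max_generations = 40, seed = 5)
  g <- ga_optimize(Xs, y, hidden = 4, cfg = cfg)
  expect_true(all(diff(g$trace$best_fitness) >= 0))
  expect_true(all(g$trace$gene_min >= cfg$h_min))
  expect_true(all(g$trace$gene_max <= cfg$h_max))
  expect_true(all(g$genome >= cfg$h_min & g$genome <= cfg$h_max))
  # determinism under the config seed
  g2 <- ga_optimize(Xs, y, hidden = 4, cfg = cfg)
  expect_identical(g$genome, g2$genome)
})

test_that("the GA solves a 1-D quadratic surrogate", {
  g <- ga_optimize(fitness_fn = function(x) 1 / ((x - 3)^2 + 1e-12),
                   genome_length = 1,
                   cfg = ga_config(pop_size = 30, max_generations = 50,
                                   h_min = -5, h_max = 5, seed = 4))
  expect_lt(abs(g$genome - 3), 0.1)
})

test_that("backprop gradients match central finite differences", {
  for (s in 1:5) {
    H <- withr::with_seed(s, sample(2:5, 1))
    m <- mlp_new(H, n_in = 3, init = "uniform", seed = s)
    dat <- withr::with_seed(s + 50,
                            list(X = matrix(runif(24), 8, 3), y = runif(8)))
    g <- crabgrade:::mlp_gradient(m, dat$X, dat$y)
    analytic <- c(g$W1, g$W2, g$th1, g$th2)
    pars <- genome_encode(m)
    eps <- 1e-6
    numeric_g <- vapply(seq_along(pars), function(i) {
      up <- pars; up[i] <- up[i] + eps
      dn <- pars; dn[i] <- dn[i] - eps
      (crabgrade:::half_mse(genome_decode(up, H, n_in = 3), dat$X, dat$y) -
       crabgrade:::half_mse(genome_decode(dn, H, n_in = 3), dat$X, dat$y)) /
        (2 * eps)
    }, numeric(1))
    expect_equal(analytic, numeric_g,
                 tolerance = 1e-6)
  }
})

test_that("backprop learns XOR and never increases the returned train error", {
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4)
  y <- c(0, 1, 1, 0)
  m <- mlp_new(4, n_in = 2, init = "uniform", seed = 2)
  E0 <- crabgrade:::half_mse(m, X, y)
  fit <- bp_train(m, X, y, train_config(epochs = 5000, learning_rate = 0.5,
                                        val_frac = 0))
  pred <- as.numeric(mlp_forward(fit$model, X) > 0.5)
  expect_equal(pred, y)
  expect_lte(fit$report$final_mse, E0)
  expect_true(fit$report$stop_reason %in%
                c("goal", "max_epochs", "min_gradient", "max_fail"))
})

test_that("validation-based early stopping engages when a carve-out exists", {
  tbl <- crab_table(seed = 6)
  X <- cbind(as.numeric(tbl$gender == "male"), tbl$weight_g,
             tbl$fatness_pct, tbl$shell_gray)
  Xs <- apply_scaling(X, fit_scaling(X))
  y <- grade_targets(3)[tbl$grade]
  m <- mlp_new(6, init = "uniform", seed = 1)
  fit <- bp_train(m, Xs, y, train_config(epochs = 200, val_frac = 0.2,
                                         max_fail = 6, seed = 3))
  expect_gt(length(fit$report$val_mse), 0)
  expect_true(fit$report$stop_reason %in% c("max_fail", "max_epochs"))
  if (fit$report$stop_reason == "max_fail")
    expect_lt(length(fit$report$train_mse), 200)
})

test_that("hidden-node selection minimizes MSE with ties to smaller nets", {
  reported <- c(`3` = 0.027966, `4` = 0.05372, `5` = 0.024212,
                `6` = 0.0081613, `7` = 0.032279)
  expect_equal(best_hidden_nodes(reported), 6)
  expect_equal(best_hidden_nodes(c(`5` = 0.1)), 5)
  expect_equal(best_hidden_nodes(c(`4` = 0.2, `6` = 0.2, `5` = 0.3)), 4)
})

test_that("hidden-node scan trains one model per candidate", {
  tbl <- crab_table(seed = 8)[1:40, ]
  X <- cbind(as.numeric(tbl$gender == "male"), tbl$weight_g,
             tbl$fatness_pct, tbl$shell_gray)
  Xs <- apply_scaling(X, fit_scaling(X))
  y <- grade_targets(3)[tbl$grade]
  scan <- select_hidden_nodes(Xs, y, candidates = c(3, 5),
                              ga_cfg = ga_config(pop_size = 15,
                                                 max_generations = 20,
                                                 seed = 2),
                              train_cfg = train_config(epochs = 200,
                                                       val_frac = 0))
  expect_named(scan$mse_map, c("3", "5"))
  expect_true(scan$best %in% c(3, 5))
  expect_equal(scan$best, best_hidden_nodes(scan$mse_map))
})

test_that("grade decoding rounds to the nearest target, halves down", {
  m <- mlp_new(2, init = "zero", grade_levels = 3)
  m$scaling <- list(min = rep(0, 4), max = rep(1, 4))
  x <- rep(0.5, 4)
  # zero net outputs 0 -> grade 1 encoding exactly
  expect_equal(predict_grade(m, x), 1L)
  m$th2 <- -0.5                      # y = 0.5, grade 2 encoding exactly
  expect_equal(predict_grade(m, x), 2L)
  m$th2 <- -0.25                     # midway 1|2 -> lower grade
  expect_equal(predict_grade(m, x), 1L)
  m$th2 <- -1.7                      # above grade 3 encoding -> clamp
  expect_equal(predict_grade(m, x), 3L)
  m$th2 <- 0.9                       # below grade 1 encoding -> clamp
  expect_equal(predict_grade(m, x), 1L)
  expect_warning(predict_grade(m, c(5, 5, 5, 5)), "clamped")
})

test_that("models survive a JSON save/load round trip", {
  m <- mlp_new(5, init = "uniform", seed = 9, grade_levels = 4)
  m$scaling <- list(min = c(0, 50, 30, 90), max = c(1, 400, 95, 200))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(m, path)
  m2 <- load_model(path)
  x <- c(1, 150, 60, 120)
  expect_equal(predict_grade(m2, x), predict_grade(m, x))
  xin <- withr::with_seed(1, runif(4))
  expect_equal(mlp_forward(m2, xin), mlp_forward(m, xin), tolerance = 1e-12)
  expect_equal(m2$grade_levels, 4L)
})
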