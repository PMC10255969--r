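#' Construct a single-hidden-layer perceptron
#'
#' The grading network is a three-layer perceptron: `n_in` inputs (the four
#' scaled features), `hidden` sigmoid units, and one linear output neuron
#' that carries the grade encoding. Thresholds are subtracted
#' (`net = W x - theta`), the classical formulation equivalent to negative
#' biases.
#'
#' @param hidden number of hidden nodes.
#' @param n_in,n_out input/output dimensions (defaults 4 and 1).
#' @param init `"zero"` for all-zero parameters or `"uniform"` for
#'   i.i.d. Uniform(-1, 1) draws (seeded).
#' @param seed seed for random initialization.
#' @param grade_levels number of quality grades G encoded on the output.
#' @return an object of class `crab_mlp`.
#' @export
mlp_new <- function(hidden, n_in = 4L, n_out = 1L,
                    init = c("zero", "uniform"), seed = 1L,
                    grade_levels = 3L) {
  init <- match.arg(init)
  stopifnot(hidden >= 1, n_in >= 1, n_out >= 1, grade_levels >= 2)
  draw <- function(n) {
    if (init == "zero") numeric(n) else runif(n, -1, 1)
  }
  pars <- with_seed(seed, draw(n_in * hidden + hidden * n_out +
                               hidden + n_out))
  m <- structure(list(
    layer_sizes = c(n_in, hidden, n_out),
    W1 = matrix(pars[seq_len(hidden * n_in)], hidden, n_in),
    W2 = matrix(pars[hidden * n_in + seq_len(n_out * hidden)], n_out, hidden),
    th1 = pars[hidden * n_in + n_out * hidden + seq_len(hidden)],
    th2 = pars[hidden * n_in + n_out * hidden + hidden + seq_len(n_out)],
    scaling = NULL,
    grade_levels = as.integer(grade_levels)
  ), class = "crab_mlp")
  m
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Forward pass
#'
#' `hidden = sigmoid(W1 x - theta1)`, `y = W2 hidden - theta2` (linear
#' output). Inputs are expected already min-max scaled to `[0, 1]`.
#'
#' @param model a `crab_mlp`.
#' @param x a length-`n_in` vector or an `n x n_in` matrix of scaled inputs.
#' @return numeric vector of network outputs (length `n`).
#' @export
mlp_forward <- function(model, x) {
  if (!inherits(model, "crab_mlp")) stop("not a crab_mlp", call. = FALSE)
  X <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(X) != model$layer_sizes[1])
    stop("input dimension mismatch", call. = FALSE)
  Hid <- sigmoid(sweep(X %*% t(model$W1), 2, model$th1))
  drop(Hid %*% t(model$W2) - rep(model$th2, each = nrow(X)))
}

#' Weighted mean squared error
#'
#' `MSE = (1/n) * sum(w_i * (y_i - yhat_i)^2)`; uniform weights by default.
#' @param pred,actual numeric vectors of equal length.
#' @param weights per-sample weights (recycled scalar allowed).
#' @export
mse <- function(pred, actual, weights = 1) {
  if (length(pred) != length(actual))
    stop("`pred` and `actual` lengths differ", call. = FALSE)
  if (length(pred) < 1) stop("empty input", call. = FALSE)
  mean(weights * (pred - actual)^2)
}

# ---- genome <-> model -------------------------------------------------------

#' Flatten a model into a real-valued GA chromosome
#'
#' Fixed layout: all weights (`W1` column-major, then `W2`), then all
#' thresholds (`theta1`, `theta2`); length `D = n_in*H + H*n_out + H + n_out`
#' (`6H + 1` for the 4-H-1 grading network).
#' @param model a `crab_mlp`.
#' @return numeric vector.
#' @export
genome_encode <- function(model) {
  c(as.vector(model$W1), as.vector(model$W2), model$th1, model$th2)
}

#' Rebuild a model from a chromosome
#' @param genome numeric vector in the [genome_encode()] layout.
#' @param hidden,n_in,n_out architecture.
#' @param grade_levels number of grades carried on the output encoding.
#' @return a `crab_mlp`.
#' @export
genome_decode <- function(genome, hidden, n_in = 4L, n_out = 1L,
                          grade_levels = 3L) {
  D <- n_in * hidden + hidden * n_out + hidden + n_out
  if (length(genome) != D)
    stop(sprintf("genome length %d does not decode to a %d-%d-%d network",
                 length(genome), n_in, hidden, n_out), call. = FALSE)
  m <- mlp_new(hidden, n_in, n_out, init = "zero",
               grade_levels = grade_levels)
  m$W1 <- matrix(genome[seq_len(hidden * n_in)], hidden, n_in)
  m$W2 <- matrix(genome[hidden * n_in + seq_len(n_out * hidden)],
                 n_out, hidden)
  m$th1 <- genome[hidden * n_in + n_out * hidden + seq_len(hidden)]
  m$th2 <- genome[hidden * n_in + n_out * hidden + hidden + seq_len(n_out)]
  m
}

# half sum-of-squares training error used by the GA
half_mse <- function(model, X, y) {
  sum((mlp_forward(model, X) - y)^2) / (2 * length(y))
}

#' GA fitness of a chromosome
#'
#' The fitness is the reciprocal of the network's training error:
#' `f = 1 / (E + eps)` with `E = SSE / (2N)` (the conventional half mean
#' squared error) and `eps = 1e-12` guarding the zero-error limit. Fitness
#' is strictly decreasing in the error, so fitter chromosomes decode to
#' better-initialized networks.
#'
#' @param genome chromosome in the [genome_encode()] layout.
#' @param X scaled `n x n_in` training inputs.
#' @param y training targets.
#' @param hidden hidden-layer size the genome decodes to.
#' @export
ga_fitness <- function(genome, X, y, hidden) {
  E <- half_mse(genome_decode(genome, hidden, n_in = ncol(X)), X, y)
  1 / (E + 1e-12)
}

#' Roulette (fitness-proportionate) selection
#'
#' Samples index `j` with probability `F_j / sum(F)`. Fitter individuals are
#' proportionally more likely to parent the next generation.
#' @param fitness non-negative fitness values, at least one positive.
#' @return the sampled index.
#' @export
roulette_select <- function(fitness) {
  if (any(fitness < 0)) stop("negative fitness", call. = FALSE)
  tot <- sum(fitness)
  if (tot <= 0) stop("degenerate population: all fitness zero", call. = FALSE)
  findInterval(runif(1) * tot, cumsum(fitness), left.open = TRUE) + 1L
}

#' Arithmetic (blend) crossover of two chromosomes
#'
#' With probability `pe` the pair crosses: for every gene `z` a fresh
#' `s ~ Uniform(0, 1)` blends the parents,
#' `a'_z = s a_z + (1 - s) b_z`, `b'_z = s b_z + (1 - s) a_z`.
#' `s = 1` reproduces the parents, `s = 0` swaps them, `s = 0.5` averages.
#' Otherwise the parents are copied unchanged.
#'
#' @param a,b parent chromosomes (equal length).
#' @param pe crossover probability.
#' @param s optional fixed blend factor(s) for deterministic use (scalar or
#'   per-gene vector); when supplied the crossover always fires.
#' @return list of two offspring chromosomes.
#' @export
crossover <- function(a, b, pe = 0.8, s = NULL) {
  if (length(a) != length(b))
    stop("parent genomes differ in length", call. = FALSE)
  if (is.null(s)) {
    if (runif(1) >= pe) return(list(a, b))
    s <- runif(length(a))
  }
  list(s * a + (1 - s) * b, s * b + (1 - s) * a)
}

#' Non-uniform (annealed, bounded) mutation
#'
#' Each gene mutates independently with probability `pm`. A mutating gene
#' moves toward the upper bound when `r2 >= 0.5` and toward the lower bound
#' otherwise, by a fraction `s1 * (1 - r / r_max)` of its distance to that
#' bound (`s1`, `r2 ~ Uniform(0, 1)`). The annealing factor `(1 - r/r_max)`
#' shrinks perturbations to zero at the final generation, so early
#' generations explore and late generations fine-tune; genes can never
#' leave `[h_min, h_max]` by construction.
#'
#' @param genome chromosome with all genes inside `[h_min, h_max]`.
#' @param pm per-gene mutation probability.
#' @param r current generation (1-based).
#' @param r_max maximum generation count.
#' @param h_min,h_max gene bounds.
#' @param s1,r2 optional fixed draws for deterministic use (scalar or
#'   per-gene); when supplied every gene mutates.
#' @return the mutated chromosome.
#' @export
mutate <- function(genome, pm = 0.1, r, r_max, h_min = -1, h_max = 1,
                   s1 = NULL, r2 = NULL) {
  stopifnot(r >= 1, r <= r_max)
  if (any(genome < h_min - 1e-12) || any(genome > h_max + 1e-12))
    stop("genome has genes outside [h_min, h_max]", call. = FALSE)
  D <- length(genome)
  forced <- !is.null(s1) || !is.null(r2)
  hit <- if (forced) rep(TRUE, D) else runif(D) < pm
  if (!any(hit)) return(genome)
  if (is.null(s1)) s1 <- runif(D)
  if (is.null(r2)) r2 <- runif(D)
  s1 <- rep_len(s1, D); r2 <- rep_len(r2, D)
  anneal <- 1 - r / r_max
  up <- r2 >= 0.5
  out <- genome
  idx <- which(hit & up)
  out[idx] <- genome[idx] + (h_max - genome[idx]) * s1[idx] * anneal
  idx <- which(hit & !up)
  out[idx] <- genome[idx] - (genome[idx] - h_min) * s1[idx] * anneal
  pmin(pmax(out, h_min), h_max)
}

#' GA configuration
#' @param pop_size population size.
#' @param pe crossover probability.
#' @param pm per-gene mutation probability.
#' @param max_generations maximum generation count `r_max`.
#' @param h_min,h_max gene bounds.
#' @param convergence_goal stop when the best half-MSE reaches this.
#' @param seed RNG seed for the GA stream.
#' @export
ga_config <- function(pop_size = 50L, pe = 0.8, pm = 0.1,
                      max_generations = 300L, h_min = -1, h_max = 1,
                      convergence_goal = 1e-5, seed = 1L) {
  stopifnot(pop_size >= 2, pe >= 0, pe <= 1, pm >= 0, pm <= 1,
            h_min < h_max, max_generations >= 1, convergence_goal > 0)
  list(pop_size = as.integer(pop_size), pe = pe, pm = pm,
       max_generations = as.integer(max_generations),
       h_min = h_min, h_max = h_max,
       convergence_goal = convergence_goal, seed = seed)
}

#' GA search for initial network weights and thresholds
#'
#' Runs initialize -> evaluate -> roulette-select / crossover / mutate with
#' elitism (the best-so-far chromosome always survives into the next
#' generation, so the best-fitness trace is non-decreasing) until the best
#' chromosome's training error `E = SSE/(2N)` reaches `convergence_goal` or
#' `max_generations` is exhausted. The best-ever chromosome is returned; its
#' decode seeds the backpropagation phase in place of random initial weights.
#'
#' @param X scaled `n x n_in` training inputs.
#' @param y training targets.
#' @param hidden hidden-layer size.
#' @param cfg a [ga_config()].
#' @param fitness_fn fitness function `(genome) -> scalar`; defaults to
#'   [ga_fitness()] on `(X, y, hidden)`. Overridable for surrogate problems.
#' @param genome_length chromosome length; derived from the architecture by
#'   default, must be given with a custom `fitness_fn` and `hidden = NULL`.
#' @return list with `genome` (best-ever), `fitness`, `mse` (its error E),
#'   `generations` run, and `trace` — a data.frame per generation with
#'   `best_fitness`, `best_mse`, `gene_min`, `gene_max` (population-wide).
#' @export
ga_optimize <- function(X = NULL, y = NULL, hidden = NULL,
                        cfg = ga_config(), fitness_fn = NULL,
                        genome_length = NULL) {
  if (is.null(fitness_fn)) {
    stopifnot(!is.null(X), !is.null(y), !is.null(hidden))
    fitness_fn <- function(g) ga_fitness(g, X, y, hidden)
    genome_length <- ncol(X) * hidden + hidden + hidden + 1L
  }
  stopifnot(!is.null(genome_length))
  with_seed(cfg$seed, {
    D <- genome_length
    pop <- matrix(runif(cfg$pop_size * D, cfg$h_min, cfg$h_max),
                  cfg$pop_size, D)
    fit <- apply(pop, 1, fitness_fn)
    best_i <- which.max(fit)
    best <- list(genome = pop[best_i, ], fitness = fit[best_i])
    trace <- vector("list", cfg$max_generations)
    gen <- 0L
    for (r in seq_len(cfg$max_generations)) {
      gen <- r
      trace[[r]] <- data.frame(
        generation = r, best_fitness = best$fitness,
        best_mse = 1 / best$fitness - 1e-12,
        gene_min = min(pop), gene_max = max(pop))
      if (1 / best$fitness - 1e-12 <= cfg$convergence_goal) break
      nxt <- matrix(0, cfg$pop_size, D)
      nxt[1, ] <- best$genome                     # elitism
      k <- 2L
      while (k <= cfg$pop_size) {
        pa <- pop[roulette_select(fit), ]
        pb <- pop[roulette_select(fit), ]
        kids <- crossover(pa, pb, cfg$pe)
        for (child in kids) {
          if (k > cfg$pop_size) break
          nxt[k, ] <- mutate(child, cfg$pm, r, cfg$max_generations,
                             cfg$h_min, cfg$h_max)
          k <- k + 1L
        }
      }
      pop <- nxt
      fit <- apply(pop, 1, fitness_fn)
      gi <- which.max(fit)
      if (fit[gi] > best$fitness)
        best <- list(genome = pop[gi, ], fitness = fit[gi])
    }
    list(genome = best$genome, fitness = best$fitness,
         mse = 1 / best$fitness - 1e-12, generations = gen,
         trace = do.call(rbind, trace[seq_len(gen)]))
  })
}

# ---- backpropagation --------------------------------------------------------

#' Training configuration for backpropagation
#' @param epochs maximum training epochs.
#' @param learning_rate gradient step size in (0, 1).
#' @param momentum momentum factor.
#' @param goal_mse stop when the training MSE/2 reaches this.
#' @param min_gradient stop when the gradient norm falls below this.
#' @param max_fail stop after this many consecutive validation-error
#'   increases (early stopping).
#' @param val_frac fraction of the training partition carved out (seeded) as
#'   the validation set driving `max_fail`.
#' @param display_every progress print period in epochs (0 = silent).
#' @param seed RNG seed for the validation carve-out.
#' @export
train_config <- function(epochs = 100L, learning_rate = 0.01,
                         momentum = 0.01, goal_mse = 1e-6,
                         min_gradient = 1e-6, max_fail = 6L,
                         val_frac = 0.2, display_every = 0L, seed = 1L) {
  stopifnot(epochs >= 1, learning_rate > 0, learning_rate < 1,
            momentum >= 0, goal_mse > 0, min_gradient > 0, max_fail >= 1,
            val_frac >= 0, val_frac < 1)
  list(epochs = as.integer(epochs), learning_rate = learning_rate,
       momentum = momentum, goal_mse = goal_mse,
       min_gradient = min_gradient, max_fail = as.integer(max_fail),
       val_frac = val_frac, display_every = as.integer(display_every),
       seed = seed)
}

# full-batch gradient of E = SSE/(2N) w.r.t. all parameters
mlp_gradient <- function(model, X, y) {
  N <- nrow(X)
  Z1 <- sweep(X %*% t(model$W1), 2, model$th1)
  Hid <- sigmoid(Z1)                              # N x H
  pred <- drop(Hid %*% t(model$W2) - rep(model$th2, each = N))
  err <- (pred - y) / N                           # N
  gW2 <- matrix(colSums(err * Hid), nrow = 1)     # 1 x H
  gth2 <- -sum(err)
  dH <- outer(err, drop(model$W2)) * Hid * (1 - Hid)  # N x H
  gW1 <- t(dH) %*% X                              # H x n_in
  gth1 <- -colSums(dH)
  list(W1 = gW1, W2 = gW2, th1 = gth1, th2 = gth2,
       E = sum((pred - y)^2) / (2 * N))
}

#' Train a network with momentum backpropagation
#'
#' Full-batch gradient descent with momentum on the half mean squared error.
#' A seeded fraction of the supplied data is held out as a validation set;
#' training stops on whichever fires first: the error goal, the epoch
#' budget, a vanishing gradient, or `max_fail` consecutive epochs in which
#' the validation error fails to improve on its best. The model with the
#' best validation error (best training error when no validation is carved)
#' is returned.
#'
#' @param model initial `crab_mlp` (typically decoded from the GA's best
#'   chromosome, or randomly initialized for the plain-BP baseline).
#' @param X scaled `n x n_in` training inputs.
#' @param y training targets.
#' @param cfg a [train_config()].
#' @return list with `model` (best) and `report` — per-epoch `train_mse`
#'   and `val_mse` traces (half-MSE), `final_mse`, `stop_reason` in
#'   `goal | max_epochs | min_gradient | max_fail`, and `val_fails`.
#' @export
bp_train <- function(model, X, y, cfg = train_config()) {
  stopifnot(inherits(model, "crab_mlp"), nrow(X) == length(y), nrow(X) >= 2)
  n <- nrow(X)
  n_val <- floor(cfg$val_frac * n)
  if (n_val >= 1 && n - n_val >= 2) {
    vi <- with_seed(child_seed(cfg$seed, "val"), sample.int(n, n_val))
    Xv <- X[vi, , drop = FALSE]; yv <- y[vi]
    Xt <- X[-vi, , drop = FALSE]; yt <- y[-vi]
  } else {
    Xv <- NULL; Xt <- X; yt <- y
  }
  vel <- list(W1 = model$W1 * 0, W2 = model$W2 * 0,
              th1 = model$th1 * 0, th2 = model$th2 * 0)
  best <- model
  best_score <- if (is.null(Xv)) half_mse(model, Xt, yt)
                else half_mse(model, Xv, yv)
  fails <- 0L
  tr_trace <- val_trace <- numeric(0)
  reason <- "max_epochs"
  for (ep in seq_len(cfg$epochs)) {
    g <- mlp_gradient(model, Xt, yt)
    if (!all(is.finite(c(g$W1, g$W2, g$th1, g$th2, g$E))))
      stop(sprintf("training diverged at epoch %d", ep), call. = FALSE)
    for (p in c("W1", "W2", "th1", "th2")) {
      vel[[p]] <- cfg$momentum * vel[[p]] - cfg$learning_rate * g[[p]]
      model[[p]] <- model[[p]] + vel[[p]]
    }
    E <- half_mse(model, Xt, yt)
    tr_trace <- c(tr_trace, E)
    if (!is.null(Xv)) {
      Ev <- half_mse(model, Xv, yv)
      val_trace <- c(val_trace, Ev)
      if (Ev < best_score) {
        best_score <- Ev; best <- model; fails <- 0L
      } else fails <- fails + 1L
    } else if (E < best_score) {
      best_score <- E; best <- model
    }
    if (cfg$display_every > 0 && ep %% cfg$display_every == 0)
      message(sprintf("epoch %d: train %.3g%s", ep, E,
                      if (is.null(Xv)) "" else
                        sprintf(", val %.3g", val_trace[ep])))
    gnorm <- sqrt(sum(c(g$W1, g$W2, g$th1, g$th2)^2))
    if (E <= cfg$goal_mse) { reason <- "goal"; break }
    if (gnorm < cfg$min_gradient) { reason <- "min_gradient"; break }
    if (!is.null(Xv) && fails >= cfg$max_fail) { reason <- "max_fail"; break }
  }
  list(model = best,
       report = list(train_mse = tr_trace, val_mse = val_trace,
                     final_mse = half_mse(best, Xt, yt),
                     stop_reason = reason, val_fails = fails))
}

#' Pick the hidden-layer size minimizing training MSE
#'
#' Trains one GA-initialized network per candidate hidden-node count on the
#' training partition and returns the candidate with the smallest training
#' mean squared error; ties go to the smaller network.
#'
#' @param X,y scaled training data.
#' @param candidates hidden-node counts to scan (default 3:7).
#' @param ga_cfg,train_cfg configurations for the two phases.
#' @param use_ga set `FALSE` to scan with plain random-init BP.
#' @return list with `best` (chosen count) and `mse_map` (named numeric of
#'   candidate -> training MSE).
#' @export
select_hidden_nodes <- function(X, y, candidates = 3:7,
                                ga_cfg = ga_config(),
                                train_cfg = train_config(),
                                use_ga = TRUE) {
  stopifnot(length(candidates) >= 1)
  mse_map <- vapply(candidates, function(H) {
    m0 <- if (use_ga) {
      g <- ga_optimize(X, y, H, cfg = ga_cfg)
      genome_decode(g$genome, H, n_in = ncol(X))
    } else {
      mlp_new(H, n_in = ncol(X), init = "uniform", seed = ga_cfg$seed)
    }
    fit <- bp_train(m0, X, y, train_cfg)
    mse(mlp_forward(fit$model, X), y)
  }, numeric(1))
  names(mse_map) <- candidates
  list(best = best_hidden_nodes(mse_map), mse_map = mse_map)
}

#' Select the hidden-node count from an MSE map
#'
#' Argmin over a named `candidate -> MSE` map; ties break toward the
#' smaller node count.
#' @param mse_map named numeric vector (names are node counts).
#' @return the chosen node count (integer).
#' @export
best_hidden_nodes <- function(mse_map) {
  stopifnot(length(mse_map) >= 1, !is.null(names(mse_map)))
  cand <- as.integer(names(mse_map))
  winners <- cand[mse_map == min(mse_map)]
  min(winners)
}

# ---- feature scaling and grade encoding -------------------------------------

#' Fit per-feature min-max scaling on the training partition
#' @param X numeric matrix (rows = specimens).
#' @return list with `min` and `max` vectors (degenerate columns widened to
#'   a unit range so scaling stays defined).
#' @export
fit_scaling <- function(X) {
  mn <- apply(X, 2, min); mx <- apply(X, 2, max)
  deg <- mx - mn < 1e-12
  mx[deg] <- mn[deg] + 1
  list(min = mn, max = mx)
}

#' Apply min-max scaling
#'
#' Maps each feature to `[0, 1]` using ranges fit on the training partition.
#' Values outside the fitted range by more than `margin` (as a fraction of
#' the range) trigger a warning; the scaled result is clamped to `[0, 1]`.
#' @param X matrix or 4-vector of raw features.
#' @param scaling a [fit_scaling()] result.
#' @param margin tolerated out-of-range fraction before warning.
#' @export
apply_scaling <- function(X, scaling, margin = 0.1) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  rng <- scaling$max - scaling$min
  Z <- sweep(sweep(X, 2, scaling$min), 2, rng, "/")
  if (any(Z < -margin) || any(Z > 1 + margin))
    warning("feature outside the training range; clamped", call. = FALSE)
  pmin(pmax(Z, 0), 1)
}

#' Equally spaced grade targets on the output neuron
#' @param G number of grades (>= 2).
#' @return numeric vector: grade g is encoded as `(g - 1) / (G - 1)`.
#' @export
grade_targets <- function(G) {
  stopifnot(G >= 2)
  (seq_len(G) - 1) / (G - 1)
}

#' Predict the quality grade of a specimen
#'
#' Scales the four features with the model's stored training-range scaling,
#' runs the forward pass, and decodes the scalar output to the nearest grade
#' target; outputs exactly midway between two targets round to the lower
#' grade, and out-of-range outputs clamp to grades 1 and G.
#'
#' @param model a trained `crab_mlp` carrying `scaling` and `grade_levels`.
#' @param features a `crab_features` object, a 4-vector in
#'   (gender, weight, fatness, shell gray) order, or a matrix of rows.
#' @return integer grade(s) in `1..G`.
#' @export
predict_grade <- function(model, features) {
  stopifnot(inherits(model, "crab_mlp"), !is.null(model$scaling))
  X <- if (inherits(features, "crab_features")) {
    matrix(feature_vector(features), nrow = 1)
  } else if (is.matrix(features)) features else matrix(features, nrow = 1)
  y <- mlp_forward(model, apply_scaling(X, model$scaling))
  G <- model$grade_levels
  g <- ceiling(y * (G - 1) - 0.5) + 1L   # nearest target, halves round down
  as.integer(pmin(pmax(g, 1L), G))
}

# ---- persistence ------------------------------------------------------------

#' Save a trained model as JSON
#' @param model a `crab_mlp`.
#' @param path output path.
#' @export
save_model <- function(model, path) {
  obj <- list(layer_sizes = model$layer_sizes,
              W1 = model$W1, W2 = model$W2,
              th1 = model$th1, th2 = model$th2,
              scaling = model$scaling, grade_levels = model$grade_levels)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}

#' Load a model saved by [save_model()]
#' @param path JSON path.
#' @return a `crab_mlp`.
#' @export
load_model <- function(path) {
  o <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mlp_new(o$layer_sizes[2], n_in = o$layer_sizes[1],
               n_out = o$layer_sizes[3], init = "zero",
               grade_levels = o$grade_levels)
  m$W1 <- matrix(o$W1, nrow = o$layer_sizes[2])
  m$W2 <- matrix(o$W2, nrow = o$layer_sizes[3])
  m$th1 <- as.numeric(o$th1); m$th2 <- as.numeric(o$th2)
  if (!is.null(o$scaling))
    m$scaling <- list(min = as.numeric(o$scaling$min),
                      max = as.numeric(o$scaling$max))
  m
}
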