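#' Seeded random train/test split
#'
#' Shuffles `1..n` and carves `round(n * (1 - train_frac))` indices for the
#' test side; the split is a partition (disjoint, exhaustive) and identical
#' for identical seeds.
#'
#' @param n number of specimens.
#' @param train_frac training fraction in (0, 1); default 0.7 for the
#'   conventional 7:3 division.
#' @param seed split seed.
#' @return list with integer vectors `train` and `test`.
#' @export
split_data <- function(n, train_frac = 0.7, seed = 1L) {
  stopifnot(n >= 2, train_frac > 0, train_frac < 1)
  n_test <- round(n * (1 - train_frac))
  if (n_test < 1 || n_test >= n)
    stop("degenerate partition: one side is empty", call. = FALSE)
  idx <- with_seed(seed, sample.int(n))
  list(train = sort(idx[seq_len(n - n_test)]),
       test = sort(idx[(n - n_test + 1):n]))
}

#' Exact-match grading accuracy in percent
#'
#' `100 * (#exact grade matches) / n`, reported to two decimals (22 of 24
#' correct is 91.67).
#' @param pred,true integer grade vectors of equal length.
#' @export
grade_accuracy <- function(pred, true) {
  if (length(pred) != length(true))
    stop("`pred` and `true` lengths differ", call. = FALSE)
  round(100 * mean(pred == true), 2)
}

encode_gender_col <- function(g) {
  if (is.numeric(g)) g else as.numeric(g == "male")
}

#' Train a GA-BPNN grader on a feature table
#'
#' One full training pass: min-max scaling fit on the supplied rows, grade
#' targets spread equally on `[0, 1]`, GA search for initial weights and
#' thresholds (skipped for the plain-BP baseline), then momentum
#' backpropagation. The returned model carries its scaling and grade count,
#' so [predict_grade()] works directly on raw features.
#'
#' @param features data.frame with the four feature columns and a grade
#'   column.
#' @param grade_col name of the grade column.
#' @param hidden hidden-node count.
#' @param ga_cfg,train_cfg phase configurations ([ga_config()],
#'   [train_config()]).
#' @param use_ga `FALSE` trains the random-initialization BP baseline.
#' @param grade_levels number of grades G; defaults to the max grade seen.
#' @return list with `model`, `report` (from [bp_train()]), and `ga`
#'   (GA result or `NULL`).
#' @export
train_grader <- function(features, grade_col = "grade", hidden = 6L,
                         ga_cfg = ga_config(), train_cfg = train_config(),
                         use_ga = TRUE, grade_levels = NULL) {
  X <- cbind(gender = encode_gender_col(features$gender),
             weight_g = features$weight_g,
             fatness_pct = features$fatness_pct,
             shell_gray = features$shell_gray)
  grades <- features[[grade_col]]
  G <- if (is.null(grade_levels)) max(grades) else as.integer(grade_levels)
  stopifnot(G >= 2, all(grades >= 1), all(grades <= G))
  scaling <- fit_scaling(X)
  Xs <- apply_scaling(X, scaling)
  y <- grade_targets(G)[grades]
  ga <- NULL
  m0 <- if (use_ga) {
    ga <- ga_optimize(Xs, y, hidden, cfg = ga_cfg)
    genome_decode(ga$genome, hidden, n_in = 4L, grade_levels = G)
  } else {
    mlp_new(hidden, init = "uniform", seed = ga_cfg$seed, grade_levels = G)
  }
  fit <- bp_train(m0, Xs, y, train_cfg)
  model <- fit$model
  model$scaling <- scaling
  model$grade_levels <- G
  list(model = model, report = fit$report, ga = ga)
}

#' Repeated random-split evaluation of the grader
#'
#' The protocol behind the headline accuracy: the labelled table is split
#' 7:3 at random `n_repeats` times (independent derived seeds), a grader is
#' trained on each training side and scored by exact-match accuracy on the
#' held-out side, and the per-repeat accuracies are averaged. Optionally a
#' hidden-node scan runs per repeat instead of a fixed size.
#'
#' @param features labelled feature table.
#' @param grade_col grade column name.
#' @param n_repeats number of random divisions (default 4).
#' @param train_frac training fraction.
#' @param hidden hidden-node count used when `scan_hidden` is off.
#' @param scan_hidden if `TRUE`, pick the hidden size per repeat with
#'   [select_hidden_nodes()] over `candidates`.
#' @param candidates hidden-node counts for the scan.
#' @param eval_col label column the test-side accuracy is scored against;
#'   defaults to the training label column. Pass the ground-truth column
#'   (e.g. `"grade_true"` of a synthetic dataset) to measure recovery of
#'   the underlying rule when the training labels are noisy.
#' @param ga_cfg,train_cfg phase configurations; their seeds are re-derived
#'   per repeat from `seed`. The default training budget is a 2000-epoch
#'   momentum descent without a validation carve-out: at this data scale a
#'   held-out validation set is too small and noisy to drive early
#'   stopping, so the epoch budget itself acts as the regularizer.
#' @param use_ga `FALSE` evaluates the plain-BP baseline.
#' @param seed master seed fanned out to split/GA/BP streams.
#' @return object of class `crab_eval_report`: `per_repeat` data.frame
#'   (repeat, accuracy, hidden, n_test), `mean_accuracy`, `confusion`
#'   (list of tables), and the config echo.
#' @export
run_experiment <- function(features, grade_col = "grade", n_repeats = 4L,
                           train_frac = 0.7, hidden = 6L,
                           scan_hidden = FALSE, candidates = 3:7,
                           eval_col = grade_col,
                           ga_cfg = ga_config(),
                           train_cfg = train_config(epochs = 2000L,
                                                    val_frac = 0),
                           use_ga = TRUE, seed = 1L) {
  stopifnot(n_repeats >= 1)
  n <- nrow(features)
  G <- max(features[[grade_col]])
  acc <- numeric(n_repeats)
  hid <- integer(n_repeats)
  n_test <- integer(n_repeats)
  confusion <- vector("list", n_repeats)
  for (rep_i in seq_len(n_repeats)) {
    sp <- split_data(n, train_frac,
                     seed = child_seed(seed, paste0("split", rep_i)))
    tr <- features[sp$train, , drop = FALSE]
    te <- features[sp$test, , drop = FALSE]
    ga_i <- ga_cfg; ga_i$seed <- child_seed(seed, paste0("ga", rep_i))
    bp_i <- train_cfg; bp_i$seed <- child_seed(seed, paste0("bp", rep_i))
    h <- hidden
    if (scan_hidden) {
      Xtr <- cbind(encode_gender_col(tr$gender), tr$weight_g,
                   tr$fatness_pct, tr$shell_gray)
      sc <- fit_scaling(Xtr)
      h <- select_hidden_nodes(apply_scaling(Xtr, sc),
                               grade_targets(G)[tr[[grade_col]]],
                               candidates, ga_i, bp_i, use_ga = use_ga)$best
    }
    grader <- train_grader(tr, grade_col, h, ga_i, bp_i, use_ga = use_ga,
                           grade_levels = G)
    Xte <- cbind(encode_gender_col(te$gender), te$weight_g,
                 te$fatness_pct, te$shell_gray)
    pred <- predict_grade(grader$model, Xte)
    acc[rep_i] <- grade_accuracy(pred, te[[eval_col]])
    hid[rep_i] <- h
    n_test[rep_i] <- nrow(te)
    confusion[[rep_i]] <- table(predicted = factor(pred, seq_len(G)),
                                actual = factor(te[[eval_col]],
                                                seq_len(G)))
  }
  structure(list(
    per_repeat = data.frame(repeat_ = seq_len(n_repeats), accuracy = acc,
                            hidden = hid, n_test = n_test),
    mean_accuracy = mean(acc),
    confusion = confusion,
    config = list(n_repeats = n_repeats, train_frac = train_frac,
                  hidden = hidden, scan_hidden = scan_hidden,
                  use_ga = use_ga, seed = seed)
  ), class = "crab_eval_report")
}

#' @export
print.crab_eval_report <- function(x, ...) {
  cat(sprintf("Grading evaluation over %d random %d/%d splits (%s)\n",
              nrow(x$per_repeat), round(100 * x$config$train_frac),
              round(100 * (1 - x$config$train_frac)),
              if (x$config$use_ga) "GA-BPNN" else "plain BP"))
  for (i in seq_len(nrow(x$per_repeat)))
    cat(sprintf("  split %d: accuracy %.2f%% (n_test = %d, hidden = %d)\n",
                i, x$per_repeat$accuracy[i], x$per_repeat$n_test[i],
                x$per_repeat$hidden[i]))
  cat(sprintf("  mean accuracy: %.1f%%\n", x$mean_accuracy))
  invisible(x)
}

#' Extract features for every specimen of a dataset
#'
#' Runs the image path of the pipeline over a synthetic dataset (or any
#' list of specimens in the same shape): preprocessing, gender calling,
#' carapace detection, fatness and shell gray, producing a measured feature
#' table comparable to the dataset's ground-truth table.
#'
#' @param ds a `crab_dataset` from [make_dataset()] with images.
#' @param hough named list of [detect_circles()] arguments; defaults scale
#'   with the dataset's calibration.
#' @param angles,scales matcher pose grid (should cover the generator's).
#' @return data.frame `id, gender, weight_g, carapace_cm, fatness_pct,
#'   shell_gray`.
#' @export
extract_dataset_features <- function(ds, hough = NULL,
                                     angles = seq(-20, 20, by = 10),
                                     scales = c(0.9, 1.0, 1.1)) {
  stopifnot(inherits(ds, "crab_dataset"), !is.null(ds$specimens))
  if (is.null(hough))
    hough <- list(min_dist = 40, param2 = 30, canny_high = 100,
                  r_min = 40, r_max = 85)
  rows <- lapply(seq_along(ds$specimens), function(i) {
    sp <- ds$specimens[[i]]
    f <- extract_features(sp$back$image, sp$abdomen$image, ds$template,
                          weight_g = ds$features$weight_g[i],
                          cm_per_px = ds$cm_per_px, hough = hough,
                          angles = angles, scales = scales)
    data.frame(id = sp$id, gender = f$gender, weight_g = f$weight_g,
               carapace_cm = f$carapace_cm, fatness_pct = f$fatness_pct,
               shell_gray = f$shell_gray, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
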