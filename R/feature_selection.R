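# Binary wrapper feature selection: a continuous optimizer position is
# thresholded to a feature mask, scored by KNN classification error plus a
# selected-size penalty, and the search is repeated over fresh stratified
# splits to form an experiment report.

#' Threshold a continuous position into a binary feature mask
#'
#' `bit_d = 1` iff `position_d > threshold` (strict).
#'
#' @param position Numeric vector with coordinates in `[0, 1]`.
#' @param threshold Selection threshold (default 0.5).
#' @return Integer 0/1 vector of the same length.
#' @export
binarize_position <- function(position, threshold = 0.5) {
  as.integer(position > threshold)
}

#' Fitness configuration for wrapper selection
#'
#' @param alpha Weight on the classification error (default 0.99); the size
#'   term gets `1 - alpha`.
#' @param threshold Binarization threshold (default 0.5).
#' @param k KNN neighbor count for the fitness classifier (default 5).
#' @param empty_mask_fitness Fitness assigned to an empty mask (default 1.0,
#'   the maximum, so empty selections are always rejected).
#' @param literal_weights Use `alpha*E + (1 - beta)*S/D` with `beta = 1 -
#'   alpha`, i.e. weight the size term by `alpha` as well (default FALSE).
#' @param cv_folds When set (e.g. 5), estimate the error by stratified
#'   k-fold cross-validation on the training partition instead of the
#'   held-out split, avoiding selection bias at extra cost (default `NULL`:
#'   held-out split, the protocol-faithful mode).
#' @return A `fitness_config` list.
#' @export
fitness_config <- function(alpha = 0.99, threshold = 0.5, k = 5,
                           empty_mask_fitness = 1.0, literal_weights = FALSE,
                           cv_folds = NULL) {
  stopifnot(alpha > 0, alpha < 1, threshold > 0, threshold < 1, k >= 1)
  if (!is.null(cv_folds)) stopifnot(cv_folds >= 2)
  structure(list(alpha = alpha, threshold = threshold, k = as.integer(k),
                 empty_mask_fitness = empty_mask_fitness,
                 literal_weights = literal_weights, cv_folds = cv_folds),
            class = "fitness_config")
}

# Deterministic stratified fold ids: members of each class are dealt
# round-robin, so folds are balanced without consuming RNG state.
cv_fold_ids <- function(y, folds) {
  id <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    id[idx] <- rep_len(seq_len(folds), length(idx))
  }
  id
}

# Combine an error rate and a selection size into the scalar fitness.
combine_fitness <- function(E, S, D, cfg) {
  size_weight <- if (isTRUE(cfg$literal_weights)) cfg$alpha else 1 - cfg$alpha
  cfg$alpha * E + size_weight * (S / D)
}

#' Wrapper fitness of a feature mask
#'
#' Fits a KNN classifier (k per `cfg`, Euclidean distance) on the training
#' partition restricted to the selected columns, measures the
#' misclassification rate `E` on the evaluation partition (or by stratified
#' cross-validation on the training partition when `cfg$cv_folds` is set),
#' and returns `alpha * E + (1 - alpha) * S/D`. An empty mask
#' short-circuits to `cfg$empty_mask_fitness` without fitting.
#'
#' @param mask 0/1 vector of length `D`.
#' @param train_x,train_y Training features (matrix) and labels.
#' @param eval_x,eval_y Evaluation features and labels.
#' @param cfg A [fitness_config()].
#' @return Scalar fitness in `[0, 1]` (under the default weights).
#' @export
subset_fitness <- function(mask, train_x, train_y, eval_x, eval_y,
                           cfg = fitness_config()) {
  if (nrow(eval_x) < 1) stop("subset_fitness: empty evaluation partition",
                             call. = FALSE)
  D <- length(mask)
  S <- sum(mask)
  if (S == 0) return(cfg$empty_mask_fitness)
  sel <- which(mask == 1)
  if (!is.null(cfg$cv_folds)) {
    fold <- cv_fold_ids(train_y, cfg$cv_folds)
    wrong <- 0L
    for (f in seq_len(cfg$cv_folds)) {
      hold <- fold == f
      pred <- class::knn(train_x[!hold, sel, drop = FALSE],
                         train_x[hold, sel, drop = FALSE],
                         factor(train_y[!hold]), k = cfg$k)
      wrong <- wrong + sum(as.character(pred) != as.character(train_y[hold]))
    }
    E <- wrong / length(train_y)
  } else {
    pred <- class::knn(train_x[, sel, drop = FALSE], eval_x[, sel, drop = FALSE],
                       factor(train_y), k = cfg$k)
    E <- mean(as.character(pred) != as.character(eval_y))
  }
  combine_fitness(E, S, D, cfg)
}

#' Stratified train/test split indices
#'
#' @param y Label vector.
#' @param test_frac Held-out fraction (default 0.2).
#' @return List with integer index vectors `train` and `test`.
#' @export
stratified_split <- function(y, test_frac = 0.2) {
  test <- integer(0)
  for (cl in unique(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_frac))
    test <- c(test, sample(idx, n_test))
  }
  test <- sort(test)
  list(train = setdiff(seq_along(y), test), test = test)
}

# Fit the reporting classifier on selected columns and predict the test set.
report_predictions <- function(mask, train_x, train_y, test_x,
                               classifier = "knn", k = 5, trees = 100) {
  sel <- which(mask == 1)
  if (length(sel) == 0) {
    # degenerate empty mask: predict the training majority class
    maj <- names(which.max(table(train_y)))[1]
    return(rep(as.integer(maj), nrow(test_x)))
  }
  if (classifier == "knn") {
    as.integer(as.character(
      class::knn(train_x[, sel, drop = FALSE], test_x[, sel, drop = FALSE],
                 factor(train_y), k = k)))
  } else if (classifier == "rf") {
    fit <- randomForest::randomForest(train_x[, sel, drop = FALSE],
                                      factor(train_y), ntree = trees)
    as.integer(as.character(stats::predict(fit, test_x[, sel, drop = FALSE])))
  } else {
    stop("unknown reporting classifier '", classifier, "' (choices: knn, rf)",
         call. = FALSE)
  }
}

#' Run one wrapper feature-selection experiment
#'
#' Draws a stratified 80/20 split, wraps the data into the KNN-error fitness,
#' runs the named optimizer (defaults P = 10, T = 50), and reports the best
#' mask with its test-set accuracy/precision/recall/F1 under the reporting
#' classifier. One agent of the initial population is seeded at 0.75 in every
#' coordinate so the full-feature baseline is always reachable.
#'
#' @param data Feature data frame (`sample_id`, features, `label`).
#' @param optimizer Optimizer name (see [get_optimizer()]) or driver function.
#' @param fitness_cfg A [fitness_config()].
#' @param P,T Population size and iterations.
#' @param seed Integer seed controlling the split and the optimizer run.
#' @param classifier Reporting classifier, `"knn"` (default) or `"rf"`.
#' @param trees Trees for the `"rf"` reporting classifier (default 100).
#' @param test_frac Held-out fraction (default 0.2).
#' @return A `selection_run` list: `mask`, `selected_count`, `best_fitness`,
#'   `trace`, `split`, `accuracy`, `precision`, `recall`, `f1`,
#'   `elapsed`, `seed`, `feature_names`.
#' @export
select_features <- function(data, optimizer = "shosca",
                            fitness_cfg = fitness_config(), P = 10, T = 50,
                            seed = 1, classifier = "knn", trees = 100,
                            test_frac = 0.2) {
  xy <- feature_xy(data)
  counts <- table(xy$y)
  if (length(counts) < 2) stop("select_features: both classes must be present",
                               call. = FALSE)
  t0 <- proc.time()[["elapsed"]]
  set.seed(seed)
  split <- stratified_split(xy$y, test_frac)
  train_x <- xy$x[split$train, , drop = FALSE]
  train_y <- xy$y[split$train]
  test_x <- xy$x[split$test, , drop = FALSE]
  test_y <- xy$y[split$test]
  D <- ncol(xy$x)
  objective <- function(position) {
    subset_fitness(binarize_position(position, fitness_cfg$threshold),
                   train_x, train_y, test_x, test_y, fitness_cfg)
  }
  driver <- get_optimizer(optimizer)
  res <- driver(objective, P = P, Dim = D, T = T, seed = seed,
                init_positions = matrix(0.75, 1, D))
  mask <- binarize_position(res$best_position, fitness_cfg$threshold)
  pred <- report_predictions(mask, train_x, train_y, test_x,
                             classifier = classifier, k = fitness_cfg$k,
                             trees = trees)
  metrics <- classification_metrics(pred, test_y)
  structure(list(mask = mask, selected_count = sum(mask),
                 best_fitness = res$best_fitness, trace = res$trace,
                 split = split,
                 accuracy = metrics[["accuracy"]],
                 precision = metrics[["precision"]],
                 recall = metrics[["recall"]], f1 = metrics[["f1"]],
                 n_test = length(test_y),
                 elapsed = proc.time()[["elapsed"]] - t0, seed = seed,
                 feature_names = xy$names,
                 algorithm = if (is.character(optimizer)) optimizer else "custom"),
            class = "selection_run")
}

#' Repeated-run feature-selection experiment
#'
#' Runs `R` independent selection experiments per algorithm, each with a
#' fresh stratified split seeded from `base_seed + r`. When several
#' algorithms are given, run `r` of every algorithm shares the same split
#' seed, so per-run metrics are paired across algorithms and ready for
#' Friedman ranking.
#'
#' @param data Feature data frame.
#' @param optimizers Character vector of optimizer names (or a single name).
#' @param R Number of runs (default 25).
#' @param fitness_cfg A [fitness_config()].
#' @param P,T Population size and iterations (defaults 10, 50).
#' @param base_seed Base seed; run `r` uses `base_seed + r`.
#' @param classifier,trees Reporting classifier settings.
#' @return An `experiment_report`: per-algorithm `runs` lists, `aggregates`
#'   (one row per algorithm), and the experiment `config`.
#' @export
run_repeated_experiment <- function(data, optimizers = "shosca", R = 25,
                                    fitness_cfg = fitness_config(), P = 10,
                                    T = 50, base_seed = 1,
                                    classifier = "knn", trees = 100) {
  if (R < 2) stop("run_repeated_experiment: R must be >= 2", call. = FALSE)
  optimizers <- as.character(optimizers)
  runs <- lapply(optimizers, function(alg) {
    lapply(seq_len(R), function(r) {
      select_features(data, optimizer = alg, fitness_cfg = fitness_cfg,
                      P = P, T = T, seed = base_seed + r,
                      classifier = classifier, trees = trees)
    })
  })
  names(runs) <- optimizers
  aggregates <- do.call(rbind, lapply(optimizers, function(alg) {
    cbind(data.frame(algorithm = alg, stringsAsFactors = FALSE),
          as.data.frame(aggregate_run_metrics(runs[[alg]])))
  }))
  structure(list(runs = runs, aggregates = aggregates,
                 config = list(optimizers = optimizers, R = R, P = P, T = T,
                               base_seed = base_seed, classifier = classifier,
                               trees = trees, fitness = unclass(fitness_cfg))),
            class = "experiment_report")
}

#' Per-run metric matrix of an experiment report (runs x algorithms)
#'
#' @param report An `experiment_report`.
#' @param metric Per-run field, e.g. `"best_fitness"`, `"accuracy"`,
#'   `"selected_count"`.
#' @return Numeric matrix with one row per run and one column per algorithm.
#' @export
report_metric_matrix <- function(report, metric = "best_fitness") {
  vals <- vapply(report$runs,
                 function(rr) vapply(rr, function(x) as.numeric(x[[metric]]),
                                     numeric(1)),
                 numeric(length(report$runs[[1]])))
  matrix(vals, ncol = length(report$runs),
         dimnames = list(NULL, names(report$runs)))
}
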