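test_that("binarization is strict at the threshold", {
  expect_equal(binarize_position(c(0.6, 0.5, 0.49)), c(1L, 0L, 0L))
  expect_equal(binarize_position(rep(0, 4)), rep(0L, 4))
  expect_equal(binarize_position(rep(1, 4)), rep(1L, 4))
})

test_that("fitness arithmetic combines error and size with the 0.99/0.01 weights", {
  cfg <- fitness_config()
  fx <- separable_fixture()
  D <- 2
  # perfectly separable, full mask: E = 0, S = D
  set.seed(1)
  expect_equal(subset_fitness(c(1, 1), fx$train_x, fx$train_y, fx$eval_x,
                              fx$eval_y, cfg), 0.01)
  # labels flipped on evaluation: E = 1, S = D
  set.seed(1)
  expect_equal(subset_fitness(c(1, 1), fx$train_x, fx$train_y, fx$eval_x,
                              1 - fx$eval_y, cfg), 1.0)
  # one planted mistake in ten, half the features: 0.99*0.1 + 0.01*0.5
  fx2 <- separable_fixture(n_wrong = 1)
  set.seed(1)
  expect_equal(subset_fitness(c(1, 0), fx2$train_x, fx2$train_y, fx2$eval_x,
                              fx2$eval_y, cfg), 0.104)
  # empty mask short-circuits to the maximal fitness
  expect_equal(subset_fitness(c(0, 0), fx$train_x, fx$train_y, fx$eval_x,
                              fx$eval_y, cfg), 1.0)
  expect_error(subset_fitness(c(1, 1), fx$train_x, fx$train_y,
                              fx$eval_x[0, , drop = FALSE], integer(0), cfg),
               "empty evaluation")
})

test_that("fitness is bounded in [0,1] and strictly increasing in mask size at fixed error", {
  cfg <- fitness_config()
  for (E in c(0, 0.17, 0.5, 1)) {
    fits <- vapply(0:50, function(S) msfs:::combine_fitness(E, S, 50, cfg),
                   numeric(1))
    expect_true(all(fits >= 0 & fits <= 1))
    expect_true(all(diff(fits) > 0))
  }
  # literal weighting puts alpha on both terms
  lit <- fitness_config(literal_weights = TRUE)
  expect_equal(msfs:::combine_fitness(0, 50, 50, lit), 0.99)
})

test_that("cross-validated fitness scores separable data near the size term", {
  cfg <- fitness_config(cv_folds = 5)
  fx <- separable_fixture(n_train = 25)
  set.seed(4)
  # perfectly separable training data: CV error 0, fitness = size term
  expect_equal(subset_fitness(c(1, 1), fx$train_x, fx$train_y, fx$eval_x,
                              fx$eval_y, cfg), 0.01)
  # fold ids are deterministic and stratified
  ids <- msfs:::cv_fold_ids(fx$train_y, 5)
  expect_equal(unname(table(ids, fx$train_y)[, 1]), rep(5, 5))
  expect_identical(ids, msfs:::cv_fold_ids(fx$train_y, 5))
})

test_that("stratified splits hold out 20% of each class", {
  y <- rep(c(0, 1), c(40, 60))
  set.seed(2)
  sp <- stratified_split(y)
  expect_length(sp$test, 8 + 12)
  expect_equal(sum(y[sp$test] == 0), 8)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), seq_along(y))
})

test_that("select_features is seed-reproducible and beats the full-feature mask", {
  tab <- make_feature_table(table_spec(n_per_class = 30, D = 12, k = 3,
                                       seed = 8))
  r1 <- select_features(tab$data, optimizer = "shosca", P = 6, T = 10, seed = 5)
  r2 <- select_features(tab$data, optimizer = "shosca", P = 6, T = 10, seed = 5)
  expect_identical(r1$mask, r2$mask)
  expect_identical(r1$accuracy, r2$accuracy)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(r1$trace <= 1, r1$trace >= 0))

  # the all-features mask is injected into the initial population, so the
  # returned fitness can never be worse than the full-mask fitness
  xy <- msfs:::feature_xy(tab$data)
  set.seed(5)
  sp <- stratified_split(xy$y)
  set.seed(5)
  full <- subset_fitness(rep(1L, ncol(xy$x)), xy$x[sp$train, ], xy$y[sp$train],
                         xy$x[sp$test, ], xy$y[sp$test], fitness_config())
  expect_lte(r1$best_fitness, full)
})

test_that("the rf reporting classifier is accepted and scores the same mask", {
  tab <- make_feature_table(table_spec(n_per_class = 25, D = 8, k = 2, seed = 3))
  r <- select_features(tab$data, optimizer = "sca", P = 5, T = 5, seed = 2,
                       classifier = "rf", trees = 50)
  expect_true(r$accuracy >= 0 && r$accuracy <= 1)
  expect_error(select_features(tab$data, optimizer = "sca", P = 5, T = 5,
                               seed = 2, classifier = "svm"),
               "unknown reporting classifier")
})

test_that("repeated experiments pair splits across algorithms and aggregate correctly", {
  tab <- make_feature_table(table_spec(n_per_class = 25, D = 10, k = 2, seed = 6))
  rep1 <- run_repeated_experiment(tab$data, optimizers = c("sho", "shosca"),
                                  R = 3, P = 5, T = 5, base_seed = 11)
  expect_equal(names(rep1$runs), c("sho", "shosca"))
  # paired: the same run index shares its train/test split across algorithms
  for (r in 1:3) {
    expect_identical(rep1$runs$sho[[r]]$split, rep1$runs$shosca[[r]]$split)
  }
  # aggregates reproduce from the stored runs
  fit <- vapply(rep1$runs$sho, `[[`, numeric(1), "best_fitness")
  agg <- rep1$aggregates[rep1$aggregates$algorithm == "sho", ]
  expect_equal(agg$mean_fitness, mean(fit))
  expect_equal(agg$best_fitness, min(fit))
  expect_equal(agg$worst_fitness, max(fit))
  expect_equal(agg$std_fitness, sd(fit))
  expect_error(run_repeated_experiment(tab$data, R = 1), "R must be")
})

test_that("metric matrices expose runs x algorithms blocks", {
  tab <- make_feature_table(table_spec(n_per_class = 25, D = 10, k = 2, seed = 6))
  rep1 <- run_repeated_experiment(tab$data, optimizers = c("sho", "sca"),
                                  R = 2, P = 5, T = 4, base_seed = 21)
  m <- report_metric_matrix(rep1, "best_fitness")
  expect_equal(dim(m), c(2L, 2L))
  expect_equal(unname(m[1, "sho"]), rep1$runs$sho[[1]]$best_fitness,
               ignore_attr = TRUE)
})
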