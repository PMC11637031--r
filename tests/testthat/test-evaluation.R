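test_that("classification metrics reproduce direct ratios", {
  # tp=3, fp=1, fn=1, tn=5
  pred <- c(1, 1, 1, 1, 0, 0, 0, 0, 0, 0)
  truth <- c(1, 1, 1, 0, 1, 0, 0, 0, 0, 0)
  cc <- confusion_counts(pred, truth)
  expect_equal(unname(cc), c(3L, 1L, 1L, 5L))
  m <- classification_metrics(pred, truth)
  expect_equal(m[["accuracy"]], 0.8)
  expect_equal(m[["precision"]], 0.75)
  expect_equal(m[["recall"]], 0.75)
  expect_equal(m[["f1"]], 0.75)

  perfect <- classification_metrics(truth, truth)
  expect_equal(unname(perfect), c(1, 1, 1, 1), ignore_attr = TRUE)
  expect_error(confusion_counts(1, c(1, 0)), "length")
})

test_that("degenerate denominators yield flagged zeros", {
  m <- classification_metrics(rep(0, 5), c(1, 1, 0, 0, 0))
  expect_equal(m[["recall"]], 0)
  expect_equal(m[["precision"]], 0)
  expect_true("precision" %in% attr(m, "degenerate"))
  # macro averaging still works on the same input
  mm <- classification_metrics(rep(0, 5), c(1, 1, 0, 0, 0), macro = TRUE)
  expect_equal(mm[["accuracy"]], 0.6)
})

test_that("aggregates follow the repeated-run formulas with the R-1 divisor", {
  mk <- function(fit, acc) {
    list(best_fitness = fit, accuracy = acc, n_test = 10, mask = rep(1L, 50),
         selected_count = 10, precision = acc, recall = acc, f1 = acc,
         elapsed = 1)
  }
  agg <- aggregate_run_metrics(list(mk(0.1, 0.9), mk(0.2, 0.8)))
  expect_equal(agg$mean_fitness, 0.15)
  expect_equal(agg$best_fitness, 0.1)
  expect_equal(agg$worst_fitness, 0.2)
  expect_equal(agg$std_fitness, sqrt(0.005), tolerance = 1e-12)  # ~0.0707
  expect_equal(agg$mean_accuracy, 0.85)
  expect_equal(agg$mean_selected, 10)
  expect_equal(agg$mean_selected_ratio, 0.2)
  # identical runs: zero spread
  agg0 <- aggregate_run_metrics(list(mk(0.3, 0.7), mk(0.3, 0.7)))
  expect_equal(agg0$std_fitness, 0)
  # pooled accuracy weights by test-set size
  r1 <- mk(0.1, 1); r2 <- mk(0.1, 0.5); r2$n_test <- 30
  expect_equal(aggregate_run_metrics(list(r1, r2))$mean_accuracy,
               (10 * 1 + 30 * 0.5) / 40)
})

test_that("mean selection size is reported as both raw count and ratio", {
  mk <- function(S) list(best_fitness = 0.1, accuracy = 1, n_test = 5,
                         mask = rep(1L, 50), selected_count = S,
                         precision = 1, recall = 1, f1 = 1, elapsed = 0)
  agg <- aggregate_run_metrics(list(mk(10), mk(20)))
  expect_equal(agg$mean_selected, 15)
  expect_equal(agg$mean_selected_ratio, 0.3)
})

test_that("Friedman ranking matches the brute-force oracle and stats::friedman.test", {
  # fixed 3-algorithm x 4-block tie-free fixture
  res <- matrix(c(0.10, 0.20, 0.30,
                  0.15, 0.10, 0.40,
                  0.20, 0.25, 0.10,
                  0.10, 0.30, 0.20), 4, 3, byrow = TRUE,
                dimnames = list(NULL, c("a", "b", "c")))
  got <- friedman_ranks(res, lower_is_better = TRUE)
  want <- oracle_friedman(res, lower_is_better = TRUE)
  expect_equal(unname(got$mean_ranks), want$mean_ranks)
  expect_equal(got$chi_square, want$chi_square, tolerance = 1e-12)
  ref <- stats::friedman.test(res)
  expect_equal(got$chi_square, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-12)
  # mean ranks average to (k+1)/2
  expect_equal(mean(got$mean_ranks), 2)
})

test_that("Friedman handles strict orderings, ties and degenerate input", {
  # same strict order in every block: ranks 1, 2, 3
  res <- matrix(rep(c(1, 2, 3), 5), 5, 3, byrow = TRUE)
  got <- friedman_ranks(res)
  expect_equal(unname(got$mean_ranks), c(1, 2, 3))
  # all equal: statistic 0, p = 1
  same <- matrix(0.5, 4, 3)
  got0 <- friedman_ranks(same)
  expect_equal(got0$chi_square, 0)
  expect_equal(unname(got0$mean_ranks), rep(2, 3))
  # rank-based: invariant under monotone transforms
  res2 <- matrix(runif(12), 4, 3)
  expect_equal(friedman_ranks(res2)$chi_square,
               friedman_ranks(log(res2 + 1))$chi_square)
  # tie correction agrees with stats::friedman.test on tied data
  tied <- matrix(c(1, 1, 2,
                   2, 1, 1,
                   1, 2, 3,
                   3, 2, 1), 4, 3, byrow = TRUE)
  expect_equal(friedman_ranks(tied)$chi_square,
               unname(stats::friedman.test(tied)$statistic), tolerance = 1e-12)
  expect_error(friedman_ranks(matrix(c(1, NA, 2, 3), 2, 2)), "missing")
  expect_error(friedman_ranks(matrix(1, 1, 3)), "blocks")
})

test_that("export_report writes the tabular layout and round-trips", {
  tab <- make_feature_table(table_spec(n_per_class = 25, D = 10, k = 2, seed = 4))
  rep1 <- run_repeated_experiment(tab$data, optimizers = c("sho", "shosca"),
                                  R = 2, P = 5, T = 4, base_seed = 31)
  out <- withr::local_tempdir()
  export_report(rep1, out)
  agg <- read.csv(file.path(out, "aggregate.csv"))
  expect_equal(names(agg), c("Algorithm", "FeatSize", "Acc", "Prec", "Rec",
                             "F1Score", "CPUTime", "Avrfit", "Stdfit",
                             "Bestfit", "Worstfit"))
  expect_equal(nrow(agg), 2)
  expect_equal(agg$Avrfit,
               rep1$aggregates$mean_fitness[match(agg$Algorithm,
                                                  rep1$aggregates$algorithm)])
  conv <- read.csv(file.path(out, "convergence.csv"))
  # T+1 trace entries (initial population + one per iteration) per run
  expect_equal(nrow(conv), 2 * 2 * 5)
  runs <- jsonlite::read_json(file.path(out, "runs.json"))
  expect_equal(length(runs$sho), 2)
  expect_equal(nchar(runs$sho[[1]]$mask), 10)
  fr <- jsonlite::read_json(file.path(out, "friedman.json"))
  expect_true(all(c("chi_square", "p_value") %in% names(fr[[1]])))
})
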