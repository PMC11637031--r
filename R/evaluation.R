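# Classification metrics, repeated-run aggregates, Friedman ranking across
# algorithms, and report export in a fixed tabular layout.

#' Confusion counts for binary MS-vs-healthy predictions
#'
#' @param predictions,labels Equal-length binary vectors; the positive class
#'   is MS (label 1).
#' @return Named integer vector `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(predictions, labels) {
  if (length(predictions) != length(labels)) {
    stop("confusion_counts: predictions and labels differ in length", call. = FALSE)
  }
  if (length(labels) < 1) stop("confusion_counts: empty input", call. = FALSE)
  p <- as.integer(predictions); t <- as.integer(labels)
  c(tp = sum(p == 1 & t == 1), fp = sum(p == 1 & t == 0),
    fn = sum(p == 0 & t == 1), tn = sum(p == 0 & t == 0))
}

#' Accuracy, precision, recall and F1 score
#'
#' Single-class metrics with MS (label 1) as the positive class. Precision
#' and recall are defined as 0 when their denominator is 0; such results
#' carry a `degenerate` attribute naming the affected metrics.
#' `macro = TRUE` instead averages precision/recall/F1 over both classes
#' treated as positive in turn.
#'
#' @param predictions,labels Binary vectors of equal length.
#' @param macro Macro-average over the two classes (default FALSE).
#' @return Named numeric vector `accuracy`, `precision`, `recall`, `f1`.
#' @export
classification_metrics <- function(predictions, labels, macro = FALSE) {
  cc <- confusion_counts(predictions, labels)
  one_class <- function(cc) {
    flagged <- character(0)
    prec <- if (cc[["tp"]] + cc[["fp"]] == 0) { flagged <- c(flagged, "precision"); 0 }
            else cc[["tp"]] / (cc[["tp"]] + cc[["fp"]])
    rec <- if (cc[["tp"]] + cc[["fn"]] == 0) { flagged <- c(flagged, "recall"); 0 }
           else cc[["tp"]] / (cc[["tp"]] + cc[["fn"]])
    f1 <- if (prec + rec == 0) 0 else 2 * prec * rec / (prec + rec)
    list(prec = prec, rec = rec, f1 = f1, flagged = flagged)
  }
  acc <- (cc[["tp"]] + cc[["tn"]]) / sum(cc)
  pos <- one_class(cc)
  if (macro) {
    neg <- one_class(c(tp = cc[["tn"]], fp = cc[["fn"]],
                       fn = cc[["fp"]], tn = cc[["tp"]]))
    out <- c(accuracy = acc, precision = (pos$prec + neg$prec) / 2,
             recall = (pos$rec + neg$rec) / 2, f1 = (pos$f1 + neg$f1) / 2)
    attr(out, "degenerate") <- union(pos$flagged, neg$flagged)
    return(out)
  }
  out <- c(accuracy = acc, precision = pos$prec, recall = pos$rec, f1 = pos$f1)
  attr(out, "degenerate") <- pos$flagged
  out
}

#' Aggregate statistics over repeated selection runs
#'
#' Mean accuracy (pooled over runs weighted by test-set size), mean/best/
#' worst/standard deviation (divisor `R - 1`) of the per-run best fitness,
#' mean selection size (raw count and as a fraction of `D`), mean
#' precision/recall/F1 and mean wall-clock time.
#'
#' @param runs List of `selection_run` records (length >= 2).
#' @return Named list of aggregate values.
#' @export
aggregate_run_metrics <- function(runs) {
  if (length(runs) < 2) stop("aggregate_run_metrics: need >= 2 runs", call. = FALSE)
  g <- function(field) vapply(runs, function(x) as.numeric(x[[field]]), numeric(1))
  fit <- g("best_fitness")
  acc <- g("accuracy")
  m <- g("n_test")
  D <- length(runs[[1]]$mask)
  list(mean_accuracy = sum(acc * m) / sum(m),
       mean_fitness = mean(fit), best_fitness = min(fit),
       worst_fitness = max(fit), std_fitness = stats::sd(fit),
       mean_selected = mean(g("selected_count")),
       mean_selected_ratio = mean(g("selected_count")) / D,
       mean_precision = mean(g("precision")), mean_recall = mean(g("recall")),
       mean_f1 = mean(g("f1")), mean_time = mean(g("elapsed")))
}

#' Friedman rank test across algorithms
#'
#' Ranks the algorithms within every block (run), ties sharing the mean
#' rank, and computes the tie-corrected chi-square statistic
#' `12 * sum_j (S_j - R(k+1)/2)^2 / (R k (k+1) - sum(t^3 - t)/(k - 1))`
#' with `S_j` the rank sums, referred to a chi-square distribution with
#' `k - 1` degrees of freedom.
#'
#' @param results Numeric matrix, blocks (runs) x algorithms; column names
#'   are used as algorithm names.
#' @param lower_is_better Rank smaller values as better (default TRUE, the
#'   fitness convention); set FALSE for accuracy-type metrics.
#' @return A `friedman_result` list: `mean_ranks`, `chi_square`, `p_value`,
#'   `blocks`, `algorithms`.
#' @export
friedman_ranks <- function(results, lower_is_better = TRUE) {
  results <- as.matrix(results)
  if (anyNA(results)) stop("friedman_ranks: missing cells", call. = FALSE)
  R <- nrow(results); k <- ncol(results)
  if (R < 2 || k < 2) {
    stop("friedman_ranks: need >= 2 blocks and >= 2 algorithms", call. = FALSE)
  }
  ranks <- t(apply(results, 1, function(row) {
    rank(if (lower_is_better) row else -row, ties.method = "average")
  }))
  S <- colSums(ranks)
  tie_term <- sum(apply(results, 1, function(row) {
    t <- table(row); sum(t^3 - t)
  }))
  denom <- R * k * (k + 1) - tie_term / (k - 1)
  chi <- if (denom <= 0) 0 else 12 * sum((S - R * (k + 1) / 2)^2) / denom
  p <- stats::pchisq(chi, df = k - 1, lower.tail = FALSE)
  algs <- colnames(results)
  if (is.null(algs)) algs <- paste0("alg", seq_len(k))
  structure(list(mean_ranks = stats::setNames(S / R, algs), chi_square = chi,
                 p_value = p, blocks = R, algorithms = algs),
            class = "friedman_result")
}

#' @export
print.friedman_result <- function(x, ...) {
  cat(sprintf("Friedman test over %d blocks: chi-square = %.4f, p = %.4g\n",
              x$blocks, x$chi_square, x$p_value))
  print(round(x$mean_ranks, 3))
  invisible(x)
}

#' Export an experiment report to CSV/JSON files
#'
#' Writes, under `out_dir`:
#' * `aggregate.csv` — one row per algorithm with columns `Algorithm`,
#'   `FeatSize`, `Acc`, `Prec`, `Rec`, `F1Score`, `CPUTime`, `Avrfit`,
#'   `Stdfit`, `Bestfit`, `Worstfit`;
#' * `runs.json` — every per-run record (mask as a 0/1 string, metrics,
#'   seed, timing);
#' * `convergence.csv` — per-iteration best fitness traces (`algorithm`,
#'   `run`, `iteration`, `best_fitness`);
#' * `boxplot.csv` — per-run metric columns for box plots;
#' * `friedman.json` — Friedman blocks per metric (when >= 2 algorithms).
#'
#' @param report An `experiment_report` from [run_repeated_experiment()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory: ", out_dir,
                                 call. = FALSE)
  agg <- report$aggregates
  table3 <- data.frame(Algorithm = agg$algorithm,
                       FeatSize = agg$mean_selected,
                       Acc = agg$mean_accuracy, Prec = agg$mean_precision,
                       Rec = agg$mean_recall, F1Score = agg$mean_f1,
                       CPUTime = agg$mean_time, Avrfit = agg$mean_fitness,
                       Stdfit = agg$std_fitness, Bestfit = agg$best_fitness,
                       Worstfit = agg$worst_fitness)
  paths <- character(0)
  p <- file.path(out_dir, "aggregate.csv")
  utils::write.csv(table3, p, row.names = FALSE)
  paths <- c(paths, p)

  run_records <- lapply(names(report$runs), function(alg) {
    lapply(report$runs[[alg]], function(r) {
      list(algorithm = alg, seed = r$seed,
           mask = paste(r$mask, collapse = ""),
           selected_count = r$selected_count, best_fitness = r$best_fitness,
           accuracy = r$accuracy, precision = r$precision, recall = r$recall,
           f1 = r$f1, elapsed = r$elapsed)
    })
  })
  names(run_records) <- names(report$runs)
  p <- file.path(out_dir, "runs.json")
  jsonlite::write_json(run_records, p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)

  conv <- do.call(rbind, lapply(names(report$runs), function(alg) {
    do.call(rbind, lapply(seq_along(report$runs[[alg]]), function(r) {
      tr <- report$runs[[alg]][[r]]$trace
      data.frame(algorithm = alg, run = r, iteration = seq_along(tr) - 1L,
                 best_fitness = tr)
    }))
  }))
  p <- file.path(out_dir, "convergence.csv")
  utils::write.csv(conv, p, row.names = FALSE)
  paths <- c(paths, p)

  box <- do.call(rbind, lapply(names(report$runs), function(alg) {
    do.call(rbind, lapply(seq_along(report$runs[[alg]]), function(r) {
      x <- report$runs[[alg]][[r]]
      data.frame(algorithm = alg, run = r, best_fitness = x$best_fitness,
                 accuracy = x$accuracy, precision = x$precision,
                 recall = x$recall, f1 = x$f1,
                 selected_count = x$selected_count)
    }))
  }))
  p <- file.path(out_dir, "boxplot.csv")
  utils::write.csv(box, p, row.names = FALSE)
  paths <- c(paths, p)

  if (length(report$runs) >= 2) {
    fr <- lapply(c(best_fitness = "best_fitness", accuracy = "accuracy"),
                 function(metric) {
      res <- friedman_ranks(report_metric_matrix(report, metric),
                            lower_is_better = metric == "best_fitness")
      list(metric = metric, mean_ranks = as.list(res$mean_ranks),
           chi_square = res$chi_square, p_value = res$p_value,
           blocks = res$blocks)
    })
    p <- file.path(out_dir, "friedman.json")
    jsonlite::write_json(fr, p, auto_unbox = TRUE, digits = NA)
    paths <- c(paths, p)
  }
  invisible(paths)
}
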