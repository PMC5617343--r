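# Evaluation protocol: per-class precision/recall/F on the percent scale,
# the all-positive trivial baseline, thread-level k-fold cross-validation,
# and normal-theory confidence intervals over re-randomized fold reruns.

#' Precision, recall and F score for a positive class
#'
#' Standard one-vs-rest definitions on the percent scale (0-100, matching
#' how such results are usually tabulated). Zero denominators yield 0 with
#' a warning. `F = 2PR/(P+R)` when `P + R > 0`, else 0.
#'
#' @param pred,gold Equal-length label vectors.
#' @param positive The class (or classes) evaluated as positive.
#' @return A tibble with one row per positive class: `class`, `tp`, `fp`,
#'   `fn`, `precision`, `recall`, `f`.
#' @export
precision_recall_f <- function(pred, gold, positive) {
  if (length(pred) != length(gold)) {
    abort("`pred` and `gold` differ in length")
  }
  rows <- lapply(positive, function(cls) {
    tp <- sum(pred == cls & gold == cls)
    fp <- sum(pred == cls & gold != cls)
    fn <- sum(pred != cls & gold == cls)
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else {
      warn(paste0("no prediction of class ", cls, "; precision set to 0"))
      0
    }
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else {
      warn(paste0("no gold instance of class ", cls, "; recall set to 0"))
      0
    }
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    tibble(class = cls, tp = tp, fp = fp, fn = fn,
      precision = p, recall = r, f = f)
  })
  bind_rows(rows)
}

#' All-positive trivial baseline
#'
#' Predicts the positive class everywhere. Its recall is 100 and its
#' precision equals the positive-class prevalence.
#'
#' @param n Number of instances, or a data frame (its row count is used).
#' @param positive The constant label to predict.
#' @return A character vector of length `n`.
#' @export
all_positive_baseline <- function(n, positive) {
  if (is.data.frame(n)) n <- nrow(n)
  rep(positive, n)
}

# seeded fold assignment over thread ids
make_folds <- function(thread_ids, k, seed) {
  withr::with_seed(seed, {
    shuffled <- sample(thread_ids)
    setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  })
}

#' Thread-level k-fold cross-validation
#'
#' Folds partition threads, not posts, so no thread context leaks between
#' training and test. For each rerun the fold assignment is re-randomized
#' with a derived seed; the per-fold scores across reruns feed
#' [resampled_ci()].
#'
#' @param corpus A corpus tibble.
#' @param labels A tibble with `post_id` and a `label` column holding the
#'   task's gold labels.
#' @param fit_fn `function(train_corpus, train_labels)` returning a model.
#' @param predict_fn `function(model, test_corpus)` returning a tibble with
#'   `post_id` and `label`.
#' @param k Number of folds.
#' @param seed Base seed; rerun `r` uses `seed + r - 1`.
#' @param positive Class (or classes) scored as positive.
#' @param reruns Number of re-randomized fold assignments.
#' @return A tibble of class `ts_cv_metrics`: one row per rerun, fold and
#'   class with `tp`, `fp`, `fn`, `precision`, `recall`, `f`.
#' @export
cross_validate <- function(corpus, labels, fit_fn, predict_fn, k = 5L,
                           seed = 1L, positive, reruns = 1L) {
  check_corpus(corpus)
  tids <- unique(corpus$thread_id)
  if (length(tids) < k) abort("fewer threads than folds")
  out <- list()
  for (r in seq_len(reruns)) {
    folds <- make_folds(tids, k, seed + r - 1L)
    for (fold in seq_len(k)) {
      test_t <- names(folds)[folds == fold]
      train_c <- corpus[!corpus$thread_id %in% test_t, ]
      test_c <- corpus[corpus$thread_id %in% test_t, ]
      train_l <- labels[labels$post_id %in% train_c$post_id, ]
      model <- fit_fn(train_c, train_l)
      pred <- predict_fn(model, test_c)
      gold <- labels[match(pred$post_id, labels$post_id), ]
      keep <- !is.na(gold$label)
      m <- precision_recall_f(pred$label[keep], gold$label[keep], positive)
      m$rerun <- r
      m$fold <- fold
      out[[length(out) + 1]] <- m
    }
  }
  res <- bind_rows(out)[, c("rerun", "fold", "class", "tp", "fp", "fn",
    "precision", "recall", "f")]
  class(res) <- c("ts_cv_metrics", class(res))
  res
}

#' Normal-theory confidence interval over resampled fold scores
#'
#' The cross-validation protocol re-randomizes the k folds several times
#' (5 x 5 = 25 scores by default usage); the interval assumes the scores
#' are normally distributed: center = mean, halfwidth =
#' z(1 - (1-level)/2) * sd / sqrt(n).
#'
#' @param scores Numeric vector of at least two performance scores.
#' @param level Confidence level (default 0.95).
#' @return A one-row tibble with `center`, `halfwidth`, `level`, `n`.
#' @export
resampled_ci <- function(scores, level = 0.95) {
  if (length(scores) < 2) abort("need at least two scores for an interval")
  z <- qnorm(1 - (1 - level) / 2)
  tibble(
    center = mean(scores),
    halfwidth = z * sd(scores) / sqrt(length(scores)),
    level = level,
    n = length(scores)
  )
}

#' Summarize cross-validation metrics with confidence intervals
#'
#' @param cv A `ts_cv_metrics` tibble.
#' @param level Confidence level.
#' @return One row per class and metric with the resampled interval.
#' @export
summarize_cv <- function(cv, level = 0.95) {
  long <- tidyr::pivot_longer(cv, c("precision", "recall", "f"),
    names_to = "metric", values_to = "score")
  long |>
    group_by(.data$class, .data$metric) |>
    summarise(resampled_ci(.data$score, level = level), .groups = "drop")
}

#' Cohen's kappa agreement between two coders
#'
#' @param a,b Equal-length label vectors.
#' @return The kappa statistic.
#' @export
cohen_kappa <- function(a, b) {
  if (length(a) != length(b)) abort("coder vectors differ in length")
  lev <- union(unique(a), unique(b))
  ta <- factor(a, levels = lev)
  tb <- factor(b, levels = lev)
  po <- mean(ta == tb)
  pe <- sum(prop.table(table(ta)) * prop.table(table(tb)))
  (po - pe) / (1 - pe)
}
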