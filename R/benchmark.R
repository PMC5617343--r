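# The packaged context-dependence experiment: on one synthetic corpus,
# cross-validate the LSTM+CNN sequence model against the engineered-feature
# lasso baseline for binary debate detection, with thread-level folds
# shared between the two models.

#' Benchmark the sequence model against the feature baseline
#'
#' Generates (or accepts) a synthetic corpus, then runs thread-level
#' k-fold cross-validation of the binary debate task for (a) the
#' CNN+highway+LSTM sequence model and (b) lasso logistic regression over
#' the engineered features, using identical fold assignments. The lexical
#' models behind the baseline's LDA/W2V blocks are trained once on the full
#' unlabeled corpus. The deliberately compact default network (16-dim
#' embeddings, 12 filters per width, 16 LSTM units, momentum SGD with weight decay, two restarts and held-out epoch selection) keeps the
#' whole experiment to a few minutes on one CPU; the paper-scale defaults
#' of [debate_config()] remain available for larger runs.
#'
#' @param sim A [sim_config()]; the default is the reference study
#'   condition (200 threads, `rho = 0.25`, `gamma = 0.8`, seed 7).
#' @param nn A [debate_config()] for the sequence model.
#' @param k Number of cross-validation folds.
#' @param cv_seed Seed for the fold assignment.
#' @param lda_k,lda_iters LDA topics and Gibbs sweeps for the baseline
#'   features.
#' @param w2v_d,w2v_iters CBOW dimensionality/passes for the baseline
#'   features.
#' @param data Optional pre-generated `list(corpus, labels)`; overrides
#'   `sim`.
#' @return A `ts_cv_metrics` tibble with a `model` column
#'   (`"lstm_cnn"` / `"lr_features"`), positive class `DEBATE`.
#' @export
run_debate_benchmark <- function(sim = sim_config(),
                                 nn = debate_config(task = "binary", d = 16L,
                                   n_filters = 12L, m = 16L, epochs = 25L,
                                   lr = 0.01, optimizer = "momentum",
                                   weight_decay = 1e-3, val_frac = 0.15,
                                   restarts = 2L, cbow_iters = 30L,
                                   seed = 11L),
                                 k = 5L, cv_seed = 1L,
                                 lda_k = 15L, lda_iters = 150L,
                                 w2v_d = 16L, w2v_iters = 30L,
                                 data = NULL) {
  gen <- data %||% generate_corpus(sim)
  corpus <- gen$corpus
  labels <- tibble(
    post_id = gen$labels$post_id,
    label = to_binary_debate(gen$labels$debate_label),
    debate_label = gen$labels$debate_label
  )

  nn_fit <- function(tr_corpus, tr_labels) {
    train_debate_model(tr_corpus,
      tibble(post_id = tr_labels$post_id, debate_label = tr_labels$debate_label),
      config = nn)
  }
  nn_predict <- function(model, te_corpus) {
    predict_debate(model, te_corpus)[, c("post_id", "label")]
  }
  cv_nn <- cross_validate(corpus, labels, nn_fit, nn_predict,
    k = k, seed = cv_seed, positive = "DEBATE")
  cv_nn$model <- "lstm_cnn"

  lda <- train_lda(corpus, k = lda_k, iters = lda_iters, seed = 101L)
  emb <- train_cbow(corpus, d = w2v_d, iters = w2v_iters, seed = 101L)
  feats <- feature_matrix(corpus, topics = lda, embeddings = emb, seed = 101L)

  lr_fit <- function(tr_corpus, tr_labels) {
    fx <- feats[match(tr_labels$post_id, feats$post_id), ]
    train_lr_baseline(fx, tr_labels$label, classes = c("NON_DEBATE", "DEBATE"),
      seed = 101L)
  }
  lr_predict <- function(model, te_corpus) {
    fx <- feats[match(te_corpus$post_id, feats$post_id), ]
    out <- predict_lr(model, fx)
    out[, c("post_id", "label")]
  }
  cv_lr <- cross_validate(corpus, labels, lr_fit, lr_predict,
    k = k, seed = cv_seed, positive = "DEBATE")
  cv_lr$model <- "lr_features"

  res <- bind_rows(cv_nn, cv_lr)
  class(res) <- c("ts_cv_metrics", class(res))
  res
}

#' Mean F gap between the two benchmarked models
#'
#' @param bench Output of [run_debate_benchmark()].
#' @return A one-row tibble with mean F per model and the difference
#'   (`lstm_cnn - lr_features`), in F points.
#' @export
benchmark_gap <- function(bench) {
  means <- bench |>
    group_by(.data$model) |>
    summarise(mean_f = mean(.data$f), .groups = "drop")
  f_nn <- means$mean_f[means$model == "lstm_cnn"]
  f_lr <- means$mean_f[means$model == "lr_features"]
  tibble(f_lstm_cnn = f_nn, f_lr_features = f_lr, gap = f_nn - f_lr)
}
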