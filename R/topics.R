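#' Fit an LDA topic model by collapsed Gibbs sampling
#'
#' Latent Dirichlet allocation over the posts of a corpus (one document per
#' post) with symmetric Dirichlet priors. Defaults follow the settings used
#' for the lexical features: `k = 15`, `alpha = 0.5`, `beta = 0.05`. The
#' returned per-topic word distributions are normalized rows.
#'
#' @param corpus A corpus tibble.
#' @param k Number of topics.
#' @param alpha,beta Dirichlet hyperparameters (document-topic, topic-word).
#' @param iters Gibbs sweeps.
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param seed Integer seed; fits are deterministic given the seed.
#' @return An object of class `lda_model`: list with `phi` (`k x |V|`
#'   topic-word matrix, rows summing to 1), `vocab`, `k`, `alpha`, `beta`.
#' @export
train_lda <- function(corpus, k = 15L, alpha = 0.5, beta = 0.05,
                      iters = 200L, min_count = 1L, seed = 1L) {
  check_corpus(corpus)
  if (nrow(corpus) == 0) abort("corpus is empty")
  if (k < 1) abort("`k` must be at least 1")
  vocab <- build_vocab(corpus, min_count = min_count)
  docs <- lapply(corpus$sentences, function(ss) {
    tokens_to_idx(flatten_tokens(ss), vocab, oov_index = 0L)
  })
  docs <- docs[vapply(docs, length, 1L) > 0]
  if (length(docs) == 0) abort("corpus has no in-vocabulary tokens")
  phi <- withr::with_seed(seed, {
    cpp_lda_train(docs, length(vocab), as.integer(k), alpha, beta, as.integer(iters))
  })
  colnames(phi) <- vocab
  structure(list(phi = phi, vocab = vocab, k = as.integer(k),
    alpha = alpha, beta = beta), class = "lda_model")
}

#' Infer topic proportions for a single post
#'
#' Folds a token vector into a fitted topic model with a short Gibbs run at
#' fixed topic-word distributions. Unknown tokens are dropped; a post with
#' no known token gets the uniform prior proportions.
#'
#' @param tokens A character vector of tokens (or a sentences list).
#' @param model An `lda_model` from [train_lda()].
#' @param iters Gibbs sweeps for the fold-in.
#' @return A length-`k` probability vector (sums to 1).
#' @details The fold-in Gibbs chain is seeded from the token content, so
#'   the inferred proportions are a deterministic function of the post:
#'   identical posts always get identical topic vectors (and similarity 1).
#' @export
infer_topics <- function(tokens, model, iters = 50L) {
  if (is.list(tokens)) tokens <- flatten_tokens(tokens)
  idx <- tokens_to_idx(tokens, model$vocab, oov_index = 0L)
  if (length(idx) == 0) {
    return(rep(1 / model$k, model$k))
  }
  content_seed <- as.integer((sum(as.numeric(idx)) * 131 + length(idx)) %% 1000003)
  withr::with_seed(content_seed, {
    cpp_lda_infer(idx, model$phi, model$alpha, as.integer(iters))
  })
}

#' @export
print.lda_model <- function(x, ...) {
  cat("LDA topic model: k =", x$k, ", |V| =", length(x$vocab),
    ", alpha =", x$alpha, ", beta =", x$beta, "\n")
  invisible(x)
}

#' Top words per topic
#'
#' @param model An `lda_model`.
#' @param n Words per topic.
#' @return A tibble with columns `topic`, `word`, `prob`.
#' @export
top_topic_words <- function(model, n = 10L) {
  rows <- lapply(seq_len(model$k), function(t) {
    ord <- order(-model$phi[t, ])[seq_len(min(n, ncol(model$phi)))]
    tibble(topic = t, word = colnames(model$phi)[ord], prob = model$phi[t, ord])
  })
  bind_rows(rows)
}
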