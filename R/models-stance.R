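# Stance classifier: the CNN post encoder with a softmax directly over the
# pooled post vector. Posts are classified independently (stance is far
# less context dependent than debate detection).

#' Configuration for the stance CNN
#'
#' @inheritParams debate_config
#' @return A list of class `stance_config`.
#' @export
stance_config <- function(d = 50L, widths = 2:5, n_filters = 100L,
                          epochs = 30L, lr = 0.05, clip = 5,
                          optimizer = c("sgd", "momentum", "adagrad"),
                          momentum = 0.9, weight_decay = 0,
                          init_embeddings = c("cbow", "random"),
                          cbow_iters = 100L, min_count = 1L,
                          fine_tune = TRUE, seed = 1L) {
  if (epochs < 1) abort("`epochs` must be at least 1")
  structure(list(
    d = as.integer(d), widths = as.integer(widths),
    n_filters = as.integer(n_filters), epochs = as.integer(epochs),
    lr = lr, clip = clip,
    optimizer = match.arg(optimizer), momentum = momentum,
    weight_decay = weight_decay,
    init_embeddings = match.arg(init_embeddings),
    cbow_iters = as.integer(cbow_iters), min_count = as.integer(min_count),
    fine_tune = isTRUE(fine_tune), seed = as.integer(seed)
  ), class = "stance_config")
}

#' Train the CNN stance classifier
#'
#' Trains on independent posts by SGD on the per-post negative
#' log-likelihood. Every post must carry a stance label (`PRO_CAM` or
#' `CON_CAM`).
#'
#' @param corpus A corpus tibble of the posts to train on.
#' @param labels A label tibble with non-missing `stance_label` for every
#'   post of `corpus`.
#' @param config A [stance_config()].
#' @param embeddings Optional precomputed embedding matrix.
#' @return An object of class `stance_model`.
#' @export
train_stance_model <- function(corpus, labels, config = stance_config(),
                               embeddings = NULL) {
  check_corpus(corpus)
  cfg <- config
  classes <- stance_classes()
  df <- left_join(corpus, labels[c("post_id", "stance_label")], by = "post_id")
  if (nrow(df) == 0) abort("empty training set")
  if (anyNA(df$stance_label)) abort("every post must have a stance label")
  df$y <- match(df$stance_label, classes)

  withr::with_seed(cfg$seed, {
    E <- init_embedding_matrix(df, cfg, embeddings)
    vocab <- colnames(E)[-ncol(E)]
    oov <- ncol(E)
    cp <- init_conv_params(cfg$d, cfg$widths, cfg$n_filters)
    h <- cfg$n_filters * length(cfg$widths)
    par <- list(
      E = E, widths = cfg$widths, conv_W = cp$conv_W, conv_b = cp$conv_b,
      Z = matrix(0, length(classes), h), bz = rep(0, length(classes))
    )
    posts <- lapply(df$sentences, function(ss) {
      as.integer(tokens_to_idx(flatten_tokens(ss), vocab, oov_index = oov))
    })
    skip <- if (cfg$fine_tune) character(0) else "E"
    trace <- numeric(cfg$epochs)
    opt <- list()
    for (ep in seq_len(cfg$epochs)) {
      total <- 0
      for (i in sample(length(posts))) {
        res <- cpp_stance_post(posts[[i]], df$y[i], par, TRUE)
        total <- total + res$loss
        g <- res$grad
        nrm <- sqrt(grad_sq_norm(g))
        scale <- if (nrm > cfg$clip) cfg$clip / nrm else 1
        u <- apply_update(par, g, opt, cfg, scale, skip = skip)
        par <- u$par
        opt <- u$opt
      }
      trace[ep] <- total / length(posts)
    }
  })
  structure(list(
    classes = classes, vocab = vocab, par = par, config = cfg,
    loss_trace = trace
  ), class = "stance_model")
}

#' Predict stance for posts
#'
#' Argmax over the two classes; exact ties resolve to `PRO_CAM`, the
#' majority stance. Posts made only of unknown tokens are handled through
#' the learned out-of-vocabulary vector.
#'
#' @param model A `stance_model`.
#' @param corpus A corpus tibble.
#' @return A tibble with `post_id`, `label`, `p_PRO_CAM`, `p_CON_CAM`.
#' @export
predict_stance <- function(model, corpus) {
  check_corpus(corpus)
  if (nrow(corpus) == 0) {
    return(tibble(post_id = character(0), label = character(0)))
  }
  oov <- length(model$vocab) + 1L
  probs <- t(vapply(corpus$sentences, function(ss) {
    idx <- as.integer(tokens_to_idx(flatten_tokens(ss), model$vocab, oov_index = oov))
    as.vector(cpp_stance_post(idx, 0L, model$par, FALSE)$probs)
  }, numeric(length(model$classes))))
  colnames(probs) <- paste0("p_", model$classes)
  bind_cols(
    tibble(
      post_id = corpus$post_id,
      label = model$classes[max.col(probs, ties.method = "first")]
    ),
    as_tibble(probs)
  )
}

#' @export
print.stance_model <- function(x, ...) {
  cat("Stance CNN classifier\n")
  cat("  classes:", paste(x$classes, collapse = ", "),
    " d =", x$config$d, ", h =", x$config$n_filters * length(x$config$widths), "\n")
  cat("  final training NLL/post:", round(utils::tail(x$loss_trace, 1), 4), "\n")
  invisible(x)
}
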