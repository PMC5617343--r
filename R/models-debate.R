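# The sequence model for debate detection: CNN post encoder with
# max-over-time pooling, highway layer, LSTM over the posts of a thread,
# and a per-post softmax (binary debate/non-debate or 4-class typed
# debate). Trained by backpropagation through time with plain SGD on one
# thread per update and global-norm gradient clipping.

#' Training configuration for the neural models
#'
#' Defaults follow the reference architecture: 50-dimensional CBOW-initialized
#' word vectors, 100 filters for each width 2-5 (400 in total), LSTM hidden
#' size 100, SGD with learning rate 0.05 and gradient clipping at 5 for 30
#' epochs with one thread (or post, for stance) per update. The LSTM hidden
#' dimension, optimizer settings and initialization source are configurable.
#'
#' @param task `"binary"` (debate vs non-debate) or `"four_class"`.
#' @param d Word embedding dimensionality.
#' @param widths Convolution filter widths.
#' @param n_filters Filters per width.
#' @param m LSTM hidden dimension.
#' @param epochs,lr,clip SGD epochs, learning rate, global-norm clip.
#' @param init_embeddings `"cbow"` (train CBOW on the training corpus) or
#'   `"random"`.
#' @param cbow_iters CBOW passes when `init_embeddings = "cbow"`.
#' @param min_count Vocabulary frequency cutoff.
#' @param val_frac Fraction of labeled training threads held out for
#'   epoch selection. When positive, the parameters of the epoch with the
#'   lowest held-out classification error are returned (early stopping by
#'   model selection), which guards against fitting noise on weakly
#'   informative data.
#' @param restarts Independent training runs (different initializations);
#'   with `val_frac > 0` the run with the lowest held-out error is kept.
#' @param ensemble With `restarts > 1`, keep every run and average their
#'   predicted label distributions at prediction time instead of selecting
#'   a single run.
#' @param fine_tune Whether word vectors are updated during training.
#' @param seed Integer seed; fixed seed with a single worker reproduces runs.
#' @return A list of class `debate_config`.
#' @export
debate_config <- function(task = c("binary", "four_class"), d = 50L,
                          widths = 2:5, n_filters = 100L, m = 100L,
                          epochs = 30L, lr = 0.05, clip = 5,
                          optimizer = c("sgd", "momentum", "adagrad"),
                          momentum = 0.9, weight_decay = 0,
                          val_frac = 0, restarts = 1L, ensemble = FALSE,
                          init_embeddings = c("cbow", "random"),
                          cbow_iters = 100L, min_count = 1L,
                          fine_tune = TRUE, seed = 1L) {
  if (epochs < 1) abort("`epochs` must be at least 1")
  if (val_frac < 0 || val_frac >= 1) abort("`val_frac` must be in [0, 1)")
  structure(list(
    task = match.arg(task), d = as.integer(d), widths = as.integer(widths),
    n_filters = as.integer(n_filters), m = as.integer(m),
    epochs = as.integer(epochs), lr = lr, clip = clip,
    optimizer = match.arg(optimizer), momentum = momentum,
    weight_decay = weight_decay, val_frac = val_frac,
    restarts = as.integer(restarts), ensemble = isTRUE(ensemble),
    init_embeddings = match.arg(init_embeddings),
    cbow_iters = as.integer(cbow_iters), min_count = as.integer(min_count),
    fine_tune = isTRUE(fine_tune), seed = as.integer(seed)
  ), class = "debate_config")
}

# shared parameter initialization helpers -----------------------------------

init_embedding_matrix <- function(corpus, cfg, embeddings = NULL) {
  if (!is.null(embeddings)) {
    vocab <- colnames(embeddings)
    E <- embeddings
  } else if (cfg$init_embeddings == "cbow") {
    E <- train_cbow(corpus, d = cfg$d, iters = cfg$cbow_iters,
      min_count = cfg$min_count, seed = cfg$seed)
    vocab <- colnames(E)
  } else {
    vocab <- build_vocab(corpus, min_count = cfg$min_count)
    E <- matrix(runif(cfg$d * length(vocab), -0.1, 0.1), cfg$d, length(vocab),
      dimnames = list(NULL, vocab))
  }
  # learned out-of-vocabulary vector as an extra trailing column
  cbind(E, `<oov>` = runif(nrow(E), -0.1, 0.1))
}

init_conv_params <- function(d, widths, n_filters) {
  conv_W <- lapply(widths, function(k) {
    sc <- sqrt(1 / (d * k))
    matrix(runif(d * k * n_filters, -sc, sc), d * k, n_filters)
  })
  conv_b <- lapply(widths, function(k) rep(0, n_filters))
  list(conv_W = conv_W, conv_b = conv_b)
}

init_debate_params <- function(E, cfg, n_classes) {
  d <- cfg$d
  h <- cfg$n_filters * length(cfg$widths)
  m <- cfg$m
  cp <- init_conv_params(d, cfg$widths, cfg$n_filters)
  sh <- sqrt(1 / h)
  sm <- sqrt(1 / m)
  um <- function(nr, nc, s) matrix(runif(nr * nc, -s, s), nr, nc)
  list(
    E = E, widths = cfg$widths, conv_W = cp$conv_W, conv_b = cp$conv_b,
    A_H = um(h, h, sh), b_H = rep(0, h),
    A_T = um(h, h, sh), b_T = rep(-2, h), # bias the carry gate open at start
    Ui = um(m, h, sh), Uf = um(m, h, sh), Uo = um(m, h, sh), Ug = um(m, h, sh),
    Vi = um(m, m, sm), Vf = um(m, m, sm), Vo = um(m, m, sm), Vg = um(m, m, sm),
    bi = rep(0, m), bf = rep(1, m), bo = rep(0, m), bg = rep(0, m),
    Z = matrix(0, n_classes, m), bz = rep(0, n_classes)
  )
}

# recursive sum of squares / SGD step over matching numeric elements
grad_sq_norm <- function(g) {
  s <- 0
  for (el in g) {
    s <- s + if (is.list(el)) grad_sq_norm(el) else sum(el^2)
  }
  s
}

# one optimizer update; `opt` carries velocity (momentum) or squared-grad
# accumulators (adagrad) with the same structure as the gradients
apply_update <- function(par, grad, opt, cfg, scale, skip = character(0)) {
  lr <- cfg$lr
  wd <- cfg$weight_decay %||% 0
  upd1 <- function(p, g, o) {
    g <- scale * g + wd * p
    switch(cfg$optimizer,
      sgd = list(p = p - lr * g, o = o),
      momentum = {
        v <- cfg$momentum * o + g
        list(p = p - lr * v, o = v)
      },
      adagrad = {
        o <- o + g^2
        list(p = p - lr * g / sqrt(o + 1e-8), o = o)
      }
    )
  }
  for (nm in names(grad)) {
    if (nm %in% skip) next
    if (is.list(grad[[nm]])) {
      if (is.null(opt[[nm]])) opt[[nm]] <- vector("list", length(grad[[nm]]))
      for (i in seq_along(grad[[nm]])) {
        if (is.null(opt[[nm]][[i]])) opt[[nm]][[i]] <- 0 * grad[[nm]][[i]]
        u <- upd1(par[[nm]][[i]], grad[[nm]][[i]], opt[[nm]][[i]])
        par[[nm]][[i]] <- u$p
        opt[[nm]][[i]] <- u$o
      }
    } else {
      if (is.null(opt[[nm]])) opt[[nm]] <- 0 * grad[[nm]]
      u <- upd1(par[[nm]], grad[[nm]], opt[[nm]])
      par[[nm]] <- u$p
      opt[[nm]] <- u$o
    }
  }
  list(par = par, opt = opt)
}

#' Train the debate sequence model
#'
#' Minimizes the summed negative log-likelihood of the per-post label
#' sequences over all labeled threads by backpropagation through time.
#' Posts without a label inside a labeled thread contribute no loss but are
#' still consumed by the LSTM (they provide context); threads with no
#' labeled post are skipped with a warning.
#'
#' @param corpus A corpus tibble; every labeled post's thread must be fully
#'   present, since the model conditions on the preceding posts.
#' @param labels A label tibble (`post_id`, `debate_label`).
#' @param config A [debate_config()].
#' @param embeddings Optional precomputed embedding matrix (overrides the
#'   `init_embeddings` setting).
#' @return An object of class `debate_model` with the fitted parameters,
#'   the vocabulary and the per-epoch mean NLL trace.
#' @export
train_debate_model <- function(corpus, labels, config = debate_config(),
                               embeddings = NULL) {
  check_corpus(corpus)
  cfg <- config
  classes <- if (cfg$task == "binary") c("NON_DEBATE", "DEBATE") else debate_classes()
  lab <- labels
  if (cfg$task == "binary") lab$debate_label <- to_binary_debate(lab$debate_label)
  df <- left_join(corpus, lab[c("post_id", "debate_label")], by = "post_id")
  df$y <- match(df$debate_label, classes)
  df$y[is.na(df$y)] <- 0L
  labeled_threads <- unique(df$thread_id[df$y > 0])
  if (length(labeled_threads) == 0) abort("no labeled posts in the training set")
  dropped <- setdiff(unique(df$thread_id), labeled_threads)
  if (length(dropped) > 0) {
    warn(paste0("skipping ", length(dropped), " thread(s) with no labeled post"))
  }
  df <- df[df$thread_id %in% labeled_threads, ]

  run_once <- function(run_seed) {
    withr::with_seed(run_seed, {
      E <- init_embedding_matrix(df, cfg, embeddings)
      vocab <- colnames(E)[-ncol(E)]
      par <- init_debate_params(E, cfg, length(classes))
      oov <- ncol(E)
      byt <- split(seq_len(nrow(df)), df$thread_id)
      thread_posts <- lapply(byt, function(ix) {
        lapply(df$sentences[ix], function(ss) {
          as.integer(tokens_to_idx(flatten_tokens(ss), vocab, oov_index = oov))
        })
      })
      thread_y <- lapply(byt, function(ix) as.integer(df$y[ix]))
      skip <- if (cfg$fine_tune) character(0) else "E"

      n_threads <- length(thread_posts)
      val_ix <- integer(0)
      if (cfg$val_frac > 0 && n_threads >= 5) {
        val_ix <- sample(n_threads, max(2L, round(cfg$val_frac * n_threads)))
      }
      train_ix <- setdiff(seq_len(n_threads), val_ix)
      n_labeled <- sum(unlist(thread_y[train_ix]) > 0)

      # classification error rate on the labeled held-out posts; unlike a
      # likelihood criterion this tracks the hard argmax decisions, and on
      # signal-free data it settles on the majority predictor
      val_err <- function(p) {
        wrong <- 0
        n <- 0
        for (vi in val_ix) {
          probs <- cpp_debate_thread(thread_posts[[vi]],
            rep(0L, length(thread_posts[[vi]])), p, FALSE)$probs
          pred <- max.col(probs, ties.method = "first")
          keep <- thread_y[[vi]] > 0
          wrong <- wrong + sum(pred[keep] != thread_y[[vi]][keep])
          n <- n + sum(keep)
        }
        wrong / max(n, 1)
      }

      trace <- numeric(cfg$epochs)
      opt <- list()
      best_par <- par
      best_err <- if (length(val_ix) > 0) val_err(par) else Inf
      for (ep in seq_len(cfg$epochs)) {
        total <- 0
        for (ti in sample(train_ix)) {
          res <- cpp_debate_thread(thread_posts[[ti]], thread_y[[ti]], par, TRUE)
          total <- total + res$loss
          g <- res$grad
          nrm <- sqrt(grad_sq_norm(g))
          scale <- if (nrm > cfg$clip) cfg$clip / nrm else 1
          u <- apply_update(par, g, opt, cfg, scale, skip = skip)
          par <- u$par
          opt <- u$opt
        }
        trace[ep] <- total / n_labeled
        if (length(val_ix) > 0) {
          err_ep <- val_err(par)
          if (err_ep < best_err) {
            best_err <- err_ep
            best_par <- par
          }
        }
      }
      if (length(val_ix) > 0) par <- best_par
      list(par = par, vocab = vocab, trace = trace,
        val_err = if (length(val_ix) > 0) best_err else NA_real_)
    })
  }

  runs <- lapply(seq_len(max(1L, cfg$restarts %||% 1L)), function(r) {
    run_once(cfg$seed + r - 1L)
  })
  errs <- vapply(runs, function(r) r$val_err, numeric(1))
  best <- if (all(is.na(errs))) runs[[1]] else runs[[which.min(errs)]]
  par_list <- if (cfg$ensemble && length(runs) > 1) {
    lapply(runs, function(r) r$par)
  } else {
    NULL
  }
  structure(list(
    task = cfg$task, classes = classes, vocab = best$vocab, par = best$par,
    par_list = par_list, config = cfg, loss_trace = best$trace
  ), class = "debate_model")
}

#' Predict per-post debate labels for threads
#'
#' Runs the fitted sequence model over each thread in order and takes the
#' argmax label at every step; exact probability ties resolve to the first
#' class, i.e. conservatively to `NON_DEBATE`.
#'
#' @param model A `debate_model`.
#' @param corpus A corpus tibble (one or more threads).
#' @return A tibble with `post_id`, `thread_id`, `label` and one probability
#'   column per class.
#' @export
predict_debate <- function(model, corpus) {
  check_corpus(corpus)
  if (nrow(corpus) == 0) {
    return(tibble(post_id = character(0), thread_id = character(0), label = character(0)))
  }
  oov <- length(model$vocab) + 1L
  par_sets <- model$par_list %||% list(model$par)
  rows <- lapply(split(seq_len(nrow(corpus)), corpus$thread_id), function(ix) {
    posts <- lapply(corpus$sentences[ix], function(ss) {
      as.integer(tokens_to_idx(flatten_tokens(ss), model$vocab, oov_index = oov))
    })
    probs <- Reduce(`+`, lapply(par_sets, function(p) {
      cpp_debate_thread(posts, rep(0L, length(posts)), p, FALSE)$probs
    })) / length(par_sets)
    colnames(probs) <- paste0("p_", model$classes)
    bind_cols(
      tibble(
        post_id = corpus$post_id[ix], thread_id = corpus$thread_id[ix],
        label = model$classes[max.col(probs, ties.method = "first")]
      ),
      as_tibble(probs)
    )
  })
  out <- bind_rows(rows)
  out[match(corpus$post_id, out$post_id), ]
}

#' @export
print.debate_model <- function(x, ...) {
  cat("Debate sequence model (CNN + highway + LSTM)\n")
  cat("  task:", x$task, " classes:", paste(x$classes, collapse = ", "), "\n")
  cat("  d =", x$config$d, ", h =", x$config$n_filters * length(x$config$widths),
    ", m =", x$config$m, ", |V| =", length(x$vocab), "\n")
  cat("  final training NLL/post:", round(utils::tail(x$loss_trace, 1), 4), "\n")
  invisible(x)
}

#' Save or load a neural model checkpoint
#'
#' Checkpoints are JSON (17 significant digits, so parameters round-trip
#' exactly and reloaded models predict bit-identically).
#'
#' @param model A `debate_model` or `stance_model`.
#' @param path Checkpoint path.
#' @return `path` (invisibly) for save; the model for load.
#' @export
save_model <- function(model, path) {
  writeLines(jsonlite::serializeJSON(model, digits = 17), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  jsonlite::unserializeJSON(paste(readLines(path, warn = FALSE), collapse = "\n"))
}
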