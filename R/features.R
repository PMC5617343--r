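# Engineered features for the lasso logistic-regression baseline:
# thread-level (NumPost, NumUser, AvgLen), post-level (name mentions,
# sentiment/CAM keyword counts, overlap with previous post, punctuation,
# time difference, signature, agree/disagree counts) and lexical blocks
# (LDA topic proportions, mean CBOW embedding, and cosine similarities
# with the previous post).

SECONDS_30_DAYS <- 30 * 86400

#' Thread-level features
#'
#' @param thread A corpus tibble restricted to the posts of one thread.
#' @return A one-row tibble with `NumPost` (posts in the thread), `NumUser`
#'   (distinct authors) and `AvgLen` (mean token count per post).
#' @export
thread_features <- function(thread) {
  check_corpus(thread, "thread")
  if (nrow(thread) == 0) abort("thread must contain at least one post")
  lens <- vapply(thread$sentences, function(s) length(flatten_tokens(s)), 1L)
  tibble(
    NumPost = nrow(thread),
    NumUser = length(unique(thread$author_id)),
    AvgLen = mean(lens)
  )
}

count_agree_disagree <- function(tokens) {
  n_agree <- 0L
  n_disagree <- sum(tokens %in% DISAGREE_VARIANTS)
  hits <- which(tokens %in% AGREE_VARIANTS)
  for (i in hits) {
    window <- tokens[max(1L, i - 2L):max(1L, i - 1L)]
    if (i == 1L) window <- character(0)
    if (any(window %in% NEGATORS)) {
      n_disagree <- n_disagree + 1L # negated "agree" counts as disagreement
    } else {
      n_agree <- n_agree + 1L
    }
  }
  c(NAgree = n_agree, NDisagree = n_disagree)
}

#' Post-level features
#'
#' Computes the eleven per-post features: `NumName` (whole-token mentions of
#' other thread participants' author ids, case-insensitive), `NumNeg` /
#' `NumPos` (sentiment adjective lists plus morphological variants),
#' `NumCAM` (CAM keyword list), `NumOverlap` (multiset intersection of
#' content tokens with the previous post, stopwords excluded; 0 for the
#' first post), `Num?` / `Num!` (punctuation token counts), `TimeDif`
#' (seconds since the previous post, clipped at 30 days, 0 for the first
#' post), `Sig` (author signature flag), and `NAgree` / `NDisagree`, where
#' an "agree" negated within the two preceding tokens counts as
#' disagreement.
#'
#' @param post A one-row corpus tibble.
#' @param prev_post The preceding post of the thread, or `NULL`.
#' @param thread The thread the post belongs to (corpus tibble).
#' @return A one-row tibble with eleven named columns.
#' @export
post_features <- function(post, prev_post, thread) {
  toks <- flatten_tokens(post$sentences[[1]])
  participants <- tolower(setdiff(unique(thread$author_id), post$author_id))
  stop_list <- ts_lexicon("stopwords")
  content <- function(x) {
    x <- x[grepl("[[:alnum:]]", x)]
    x[!x %in% stop_list]
  }
  overlap <- 0L
  timedif <- 0
  if (!is.null(prev_post) && nrow(prev_post) > 0) {
    prev_toks <- flatten_tokens(prev_post$sentences[[1]])
    a <- table(content(toks))
    b <- table(content(prev_toks))
    common <- intersect(names(a), names(b))
    overlap <- sum(pmin(as.integer(a[common]), as.integer(b[common])))
    timedif <- min(
      as.numeric(difftime(post$timestamp, prev_post$timestamp, units = "secs")),
      SECONDS_30_DAYS
    )
  }
  ad <- count_agree_disagree(toks)
  tibble(
    NumName = sum(toks %in% participants),
    NumNeg = sum(toks %in% ts_lexicon("negative")),
    NumPos = sum(toks %in% ts_lexicon("positive")),
    NumCAM = sum(toks %in% ts_lexicon("cam")),
    NumOverlap = overlap,
    `Num?` = sum(toks == "?"),
    `Num!` = sum(toks == "!"),
    TimeDif = timedif,
    Sig = as.numeric(post$has_signature %||% 0),
    NAgree = unname(ad["NAgree"]),
    NDisagree = unname(ad["NDisagree"])
  )
}

#' Lexical features from topic and embedding models
#'
#' `LDA` is the inferred topic-proportion vector of the post, `W2V` the mean
#' of its token embeddings (zero vector when no token is known), and the
#' `*_sim` values are cosine similarities with the previous post's
#' corresponding vector (0 for the first post of a thread or when either
#' vector is zero).
#'
#' @param post,prev_post One-row corpus tibbles (`prev_post` may be `NULL`).
#' @param topics A fitted [train_lda()] model, or `NULL` to skip the block.
#' @param embeddings A [train_cbow()] matrix, or `NULL` to skip the block.
#' @param infer_iters Gibbs iterations for per-post topic inference.
#' @return A one-row tibble with columns `lda_1..k`, `lda_sim`,
#'   `w2v_1..d`, `w2v_sim` (whichever models were supplied).
#' @export
lexical_features <- function(post, prev_post = NULL, topics = NULL,
                             embeddings = NULL, infer_iters = 50L) {
  toks <- flatten_tokens(post$sentences[[1]])
  prev_toks <- if (is.null(prev_post) || nrow(prev_post) == 0) {
    NULL
  } else {
    flatten_tokens(prev_post$sentences[[1]])
  }
  out <- list()
  if (!is.null(topics)) {
    th <- infer_topics(toks, topics, iters = infer_iters)
    sim <- 0
    if (!is.null(prev_toks)) {
      sim <- cosine_similarity(th, infer_topics(prev_toks, topics, iters = infer_iters))
    }
    block <- as.list(setNames(th, paste0("lda_", seq_along(th))))
    block$lda_sim <- sim
    out <- c(out, block)
  }
  if (!is.null(embeddings)) {
    v <- mean_embedding(toks, embeddings)
    sim <- 0
    if (!is.null(prev_toks)) {
      sim <- cosine_similarity(v, mean_embedding(prev_toks, embeddings))
    }
    block <- as.list(setNames(v, paste0("w2v_", seq_along(v))))
    block$w2v_sim <- sim
    out <- c(out, block)
  }
  if (length(out) == 0) {
    return(tibble::new_tibble(list(), nrow = 1L))
  }
  as_tibble(out)
}

mean_embedding <- function(tokens, embeddings) {
  idx <- match(tokens, colnames(embeddings))
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) {
    return(rep(0, nrow(embeddings)))
  }
  rowMeans(embeddings[, idx, drop = FALSE])
}

#' Full Table-style feature matrix for a corpus
#'
#' Applies [thread_features()], [post_features()] and (when models are
#' given) [lexical_features()] to every post of the corpus. The corpus is
#' never mutated.
#'
#' @param corpus A corpus tibble.
#' @inheritParams lexical_features
#' @param seed Seed for the (Gibbs) topic inference of new posts.
#' @return A tibble with one row per post, `post_id` and `thread_id` first.
#' @export
feature_matrix <- function(corpus, topics = NULL, embeddings = NULL,
                           infer_iters = 50L, seed = 1L) {
  check_corpus(corpus)
  withr::with_seed(seed, {
    rows <- lapply(split(seq_len(nrow(corpus)), corpus$thread_id), function(ix) {
      thread <- corpus[ix, ]
      tf <- thread_features(thread)
      per_post <- lapply(seq_len(nrow(thread)), function(i) {
        prev <- if (i > 1) thread[i - 1, ] else NULL
        bind_cols(
          tibble(post_id = thread$post_id[i], thread_id = thread$thread_id[i]),
          tf,
          post_features(thread[i, ], prev, thread),
          lexical_features(thread[i, ], prev, topics, embeddings, infer_iters)
        )
      })
      bind_rows(per_post)
    })
    out <- bind_rows(rows)
    out[match(corpus$post_id, out$post_id), ]
  })
}

#' Export a feature matrix to CSV
#'
#' @param features A tibble from [feature_matrix()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_features <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}
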