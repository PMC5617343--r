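#' Train CBOW word embeddings on a corpus
#'
#' Continuous bag-of-words embeddings with negative sampling, trained
#' sentence by sentence with a dynamically sampled context window (the
#' word2vec convention). Deterministic for a fixed seed (single worker).
#' Used both as the lexical `W2V` feature block and to initialize the
#' word vectors of the neural classifiers.
#'
#' @param corpus A corpus tibble.
#' @param d Embedding dimensionality (default 50).
#' @param iters Passes over the corpus (default 100).
#' @param window Maximum context window half-width.
#' @param negative Number of negative samples per target word.
#' @param alpha Initial learning rate (linearly decayed).
#' @param min_count Minimum token frequency to enter the vocabulary.
#' @param seed Integer seed.
#' @return A `d x |V|` numeric matrix with vocabulary words as column names.
#' @export
train_cbow <- function(corpus, d = 50L, iters = 100L, window = 5L,
                       negative = 5L, alpha = 0.05, min_count = 1L, seed = 1L) {
  check_corpus(corpus)
  if (nrow(corpus) == 0) abort("corpus is empty")
  vocab <- build_vocab(corpus, min_count = min_count)
  sents <- unlist(lapply(corpus$sentences, function(ss) {
    lapply(ss, function(s) tokens_to_idx(s, vocab, oov_index = 0L))
  }), recursive = FALSE)
  sents <- sents[vapply(sents, length, 1L) >= 2L]
  if (length(sents) == 0) abort("corpus has no sentence with two known tokens")
  emb <- withr::with_seed(seed, {
    cpp_cbow_train(sents, length(vocab), as.integer(d), as.integer(window),
      as.integer(negative), as.integer(iters), alpha)
  })
  colnames(emb) <- vocab
  emb
}

#' Serialize embeddings in the whitespace text format
#'
#' Header line `vocab_size dim`, then one word and `d` floats per line.
#'
#' @param embeddings A matrix from [train_cbow()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(embeddings, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(ncol(embeddings), nrow(embeddings)), con)
  for (j in seq_len(ncol(embeddings))) {
    writeLines(paste(
      colnames(embeddings)[j],
      paste(formatC(embeddings[, j], format = "g", digits = 17), collapse = " ")
    ), con)
  }
  invisible(path)
}

#' @rdname write_embeddings
#' @export
read_embeddings <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- as.integer(strsplit(lines[1], " ")[[1]])
  words <- character(hdr[1])
  emb <- matrix(0, hdr[2], hdr[1])
  for (j in seq_len(hdr[1])) {
    parts <- strsplit(lines[j + 1], " ")[[1]]
    words[j] <- parts[1]
    emb[, j] <- as.numeric(parts[-1])
  }
  colnames(emb) <- words
  emb
}
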