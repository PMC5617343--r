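#' Cosine similarity between two numeric vectors
#'
#' Returns 0 when either vector has zero norm, the convention used for
#' similarity features of first posts in a thread.
#'
#' @param a,b Numeric vectors of equal length.
#' @return A number in \[-1, 1\].
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  na <- sqrt(sum(a^2))
  nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    return(0)
  }
  sum(a * b) / (na * nb)
}

# numerically stable softmax over a vector of logits
softmax_stable <- function(logits) {
  z <- logits - max(logits)
  e <- exp(z)
  e / sum(e)
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# flat token vector of one post (sentences is a list of character vectors)
flatten_tokens <- function(sentences) {
  if (length(sentences) == 0) character(0) else unlist(sentences, use.names = FALSE)
}

# deterministic vocabulary: words by decreasing count, ties alphabetical
build_vocab <- function(corpus, min_count = 1) {
  toks <- unlist(lapply(corpus$sentences, flatten_tokens), use.names = FALSE)
  if (length(toks) == 0) {
    abort("cannot build a vocabulary from a corpus with no tokens")
  }
  tab <- table(toks)
  tab <- tab[tab >= min_count]
  ord <- order(-as.integer(tab), names(tab))
  names(tab)[ord]
}

# map tokens to 1-based indices over vocab, unknowns -> oov_index (0 drops them)
tokens_to_idx <- function(tokens, vocab, oov_index = length(vocab) + 1L) {
  idx <- match(tokens, vocab)
  if (oov_index == 0L) {
    idx[!is.na(idx)]
  } else {
    idx[is.na(idx)] <- oov_index
    idx
  }
}

check_corpus <- function(corpus, arg = "corpus") {
  need <- c("post_id", "thread_id", "author_id", "timestamp", "text", "sentences")
  miss <- setdiff(need, names(corpus))
  if (length(miss) > 0) {
    abort(paste0("`", arg, "` is missing column(s): ", paste(miss, collapse = ", ")))
  }
  invisible(corpus)
}
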