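# Keyword lists used by the engineered features. The base adjective lists,
# CAM keywords and the stopword list ship as one-term-per-line files under
# inst/extdata; morphological variants are generated by a fixed suffix table
# so that e.g. "frustrated" also matches "frustrating" and "frustratedly".

read_lexicon_file <- function(name) {
  path <- system.file("extdata", paste0(name, ".txt"), package = "threadstance")
  if (path == "") {
    # during in-source testing before installation
    path <- file.path("inst", "extdata", paste0(name, ".txt"))
  }
  tolower(trimws(readLines(path, warn = FALSE)))
}

# fixed suffix rules: w, w+s, w+ly, and the ed <-> ing alternation
morph_variants <- function(words) {
  out <- unlist(lapply(words, function(w) {
    v <- c(w, paste0(w, "s"), paste0(w, "ly"))
    if (endsWith(w, "ed")) v <- c(v, sub("ed$", "ing", w))
    if (endsWith(w, "ing")) v <- c(v, sub("ing$", "ed", w))
    v
  }), use.names = FALSE)
  sort(unique(out))
}

#' Lexicons behind the engineered features
#'
#' `"positive"` and `"negative"` return the sentiment adjective lists
#' expanded with morphological variants, `"cam"` the CAM keyword list,
#' `"stopwords"` the stopword list used by the `NumOverlap` feature.
#'
#' @param name One of `"positive"`, `"negative"`, `"cam"`, `"stopwords"`.
#' @return A character vector of lowercased terms.
#' @export
ts_lexicon <- function(name = c("positive", "negative", "cam", "stopwords")) {
  name <- match.arg(name)
  key <- paste0("lex_", name)
  if (is.null(the[[key]])) {
    the[[key]] <- switch(name,
      positive = morph_variants(read_lexicon_file("positive_words")),
      negative = morph_variants(read_lexicon_file("negative_words")),
      cam = read_lexicon_file("cam_keywords"),
      stopwords = read_lexicon_file("stopwords")
    )
  }
  the[[key]]
}

AGREE_VARIANTS <- c("agree", "agrees", "agreed", "agreeing")
DISAGREE_VARIANTS <- c("disagree", "disagrees", "disagreed", "disagreeing")
NEGATORS <- c("not", "don't", "dont", "never", "cannot", "can't", "no")
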