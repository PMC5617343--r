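# Reading, preprocessing and sampling of threaded forum corpora.
#
# A corpus is a tibble with one row per post and columns
#   post_id, thread_id, author_id, timestamp (POSIXct, UTC), text,
#   has_signature (0/1), sentences (list of lowercased token vectors),
# sorted by thread_id, then timestamp (ties by post_id).

EMOTICON_TABLE <- c(
  ":-)" = "EMO_SMILE", ":)" = "EMO_SMILE", ":-D" = "EMO_GRIN", ":D" = "EMO_GRIN",
  ":-(" = "EMO_FROWN", ":(" = "EMO_FROWN", ";-)" = "EMO_WINK", ";)" = "EMO_WINK",
  ":'(" = "EMO_CRY", ":-P" = "EMO_TONGUE", ":P" = "EMO_TONGUE", "<3" = "EMO_HEART"
)

# abbreviations whose trailing period never ends a sentence
ABBREVIATIONS <- c("dr", "mr", "mrs", "ms", "prof", "st", "vs", "etc", "approx")

#' Preprocess raw post text into sentences of tokens
#'
#' Emoticons are substituted by `EMO_*` code tokens, non-ASCII content is
#' stripped, sentences are split on `.`/`?`/`!` followed by whitespace and a
#' capital letter (with an abbreviation guard), and each sentence is
#' tokenized on whitespace and punctuation. Question and exclamation marks
#' are kept as tokens (they feed the `Num?`/`Num!` features); sentence-final
#' periods are consumed. All tokens except the `EMO_*` codes are lowercased.
#' The function is deterministic and returns an empty list for empty input.
#'
#' @param raw_text A character scalar (may be empty or `NA`).
#' @return A list of character vectors, one per sentence.
#' @examples
#' preprocess_post("I tried laetrile. It helped!")
#' @export
preprocess_post <- function(raw_text) {
  if (length(raw_text) != 1 || is.na(raw_text)) {
    return(list())
  }
  txt <- raw_text
  # emoticons first (longest patterns first so ":-)" wins over ":)")
  pats <- names(EMOTICON_TABLE)[order(-nchar(names(EMOTICON_TABLE)))]
  for (p in pats) {
    txt <- gsub(p, paste0(" ", EMOTICON_TABLE[[p]], " "), txt, fixed = TRUE)
  }
  # strip remaining non-ASCII content
  txt <- gsub("[^\x01-\x7F]", " ", txt, useBytes = TRUE)
  if (!grepl("[[:alnum:]]", txt)) {
    return(list())
  }
  # protect abbreviation periods with a control placeholder
  txt <- stringr::str_replace_all(
    txt,
    stringr::regex(paste0("\\b(", paste(ABBREVIATIONS, collapse = "|"), ")\\."),
      ignore_case = TRUE
    ),
    "\\1\x01"
  )
  txt <- gsub("e.g.", "e\x01g\x01", txt, fixed = TRUE)
  txt <- gsub("i.e.", "i\x01e\x01", txt, fixed = TRUE)
  # sentence boundaries: terminal punctuation, whitespace, capital (or quote)
  sents <- stringr::str_split(txt, "(?<=[.?!])\\s+(?=[A-Z\"'(])")[[1]]
  out <- lapply(sents, function(s) {
    s <- gsub("([,;:!?()\"])", " \\1 ", s)
    s <- gsub("\\.(?=\\s|$)", " ", s, perl = TRUE) # sentence-final periods go
    toks <- strsplit(stringr::str_squish(s), " ", fixed = TRUE)[[1]]
    toks <- toks[nzchar(toks) & toks != "."]
    toks <- gsub("\x01", ".", toks, fixed = TRUE)
    is_emo <- startsWith(toks, "EMO_")
    toks[!is_emo] <- tolower(toks[!is_emo])
    toks
  })
  out[vapply(out, length, 1L) > 0]
}

parse_ts <- function(x) {
  # ISO-8601; timestamps without a timezone are taken as UTC
  out <- readr::parse_datetime(x)
  attr(out, "tzone") <- "UTC"
  out
}

#' Read a threaded forum corpus from JSONL
#'
#' One JSON object per line with fields `post_id`, `thread_id`, `author_id`,
#' `timestamp` (ISO-8601, UTC assumed when no zone is given) and `text`;
#' an optional boolean `has_signature` is carried through for the `Sig`
#' feature. Posts are grouped by thread and sorted ascending by timestamp
#' (ties broken by `post_id`), and [preprocess_post()] is applied to every
#' post.
#'
#' @param path Path to a JSONL file.
#' @return A corpus tibble (see Details in the package vignette).
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (length(keep) == 0) {
    abort(paste0("no posts found in ", path))
  }
  need <- c("post_id", "thread_id", "author_id", "timestamp", "text")
  rows <- lapply(keep, function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[[i]]),
      error = function(e) abort(paste0("malformed JSON on line ", i, ": ", conditionMessage(e)))
    )
    miss <- setdiff(need, names(rec))
    if (length(miss) > 0) {
      abort(paste0("line ", i, " is missing field(s): ", paste(miss, collapse = ", ")))
    }
    tibble(
      post_id = as.character(rec$post_id),
      thread_id = as.character(rec$thread_id),
      author_id = as.character(rec$author_id),
      timestamp_raw = as.character(rec$timestamp),
      text = as.character(rec$text),
      has_signature = as.numeric(rec$has_signature %||% 0)
    )
  })
  df <- bind_rows(rows)
  dup <- df$post_id[duplicated(df$post_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate post_id(s): ", paste(unique(dup), collapse = ", ")))
  }
  df$timestamp <- parse_ts(df$timestamp_raw)
  if (anyNA(df$timestamp)) {
    bad <- keep[which(is.na(df$timestamp))[1]]
    abort(paste0("unparseable timestamp on line ", bad))
  }
  df$timestamp_raw <- NULL
  df$sentences <- lapply(df$text, preprocess_post)
  df |>
    arrange(.data$thread_id, .data$timestamp, .data$post_id) |>
    select("post_id", "thread_id", "author_id", "timestamp", "text",
      "has_signature", "sentences") |>
    as_tibble()
}

#' Write a corpus back to JSONL
#'
#' Inverse of [read_corpus()] up to preprocessing (only the raw fields are
#' written).
#'
#' @param corpus A corpus tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  check_corpus(corpus)
  lines <- vapply(seq_len(nrow(corpus)), function(i) {
    jsonlite::toJSON(list(
      post_id = corpus$post_id[i],
      thread_id = corpus$thread_id[i],
      author_id = corpus$author_id[i],
      timestamp = format(corpus$timestamp[i], "%Y-%m-%dT%H:%M:%SZ", tz = "UTC"),
      text = corpus$text[i],
      has_signature = corpus$has_signature[i]
    ), auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Debate and stance label sets
#'
#' Debate labels are `NON_DEBATE`, `CAM_DEBATE`, `BC_DEBATE`, `OTHER_DEBATE`;
#' the binary view collapses the last three to `DEBATE`. Stance labels
#' (`PRO_CAM`, `CON_CAM`) are defined only for `CAM_DEBATE` posts.
#'
#' @return A character vector of label names.
#' @export
debate_classes <- function() c("NON_DEBATE", "CAM_DEBATE", "BC_DEBATE", "OTHER_DEBATE")

#' @rdname debate_classes
#' @export
stance_classes <- function() c("PRO_CAM", "CON_CAM")

#' @rdname debate_classes
#' @param labels A character vector of 4-class debate labels.
#' @export
to_binary_debate <- function(labels) {
  bad <- setdiff(unique(labels[!is.na(labels)]), debate_classes())
  if (length(bad) > 0) {
    abort(paste0("unknown debate label(s): ", paste(bad, collapse = ", ")))
  }
  ifelse(labels == "NON_DEBATE", "NON_DEBATE", "DEBATE")
}

#' Read or write a post label file
#'
#' CSV with header `post_id,debate_label[,stance_label]`; label values are
#' validated against [debate_classes()] and [stance_classes()].
#'
#' @param path A CSV file path.
#' @return A tibble with columns `post_id`, `debate_label` and (possibly
#'   `NA`) `stance_label`.
#' @export
read_labels <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (!all(c("post_id", "debate_label") %in% names(df))) {
    abort("label file must have columns post_id, debate_label")
  }
  if (!"stance_label" %in% names(df)) df$stance_label <- NA_character_
  bad <- setdiff(unique(df$debate_label[!is.na(df$debate_label)]), debate_classes())
  if (length(bad) > 0) abort(paste0("unknown debate label(s): ", paste(bad, collapse = ", ")))
  bads <- setdiff(unique(df$stance_label[!is.na(df$stance_label)]), stance_classes())
  if (length(bads) > 0) abort(paste0("unknown stance label(s): ", paste(bads, collapse = ", ")))
  df[c("post_id", "debate_label", "stance_label")]
}

#' @rdname read_labels
#' @param labels A label tibble as returned by [read_labels()].
#' @export
write_labels <- function(labels, path) {
  readr::write_csv(labels, path)
  invisible(path)
}

#' Sample posts for manual coding, covering every thread
#'
#' Allocates a base sample of size `n` across threads proportionally to
#' thread length (largest-remainder rounding), then guarantees that every
#' represented thread contributes at least one post, so the result may
#' exceed `n` by up to the number of threads. When `n` is smaller than the
#' number of threads, `n` threads are drawn with probability proportional
#' to their length and one post is taken from each. Sampling within a
#' thread is without replacement and seeded.
#'
#' @param corpus A corpus tibble (or any data frame with `post_id` and
#'   `thread_id` columns).
#' @param n Base sample size (positive integer).
#' @param seed Integer seed; the same seed gives a bit-identical sample.
#' @return A tibble with columns `post_id`, `thread_id`.
#' @export
sample_for_coding <- function(corpus, n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n <= 0) {
    abort("`n` must be a positive integer")
  }
  n <- as.integer(n)
  sizes <- table(corpus$thread_id)
  tids <- names(sizes)
  sz <- as.integer(sizes)
  withr::with_seed(seed, {
    if (n < length(tids)) {
      pick <- sample(tids, n, prob = sz)
      alloc <- setNames(integer(length(tids)), tids)
      alloc[pick] <- 1L
    } else {
      alloc <- largest_remainder(n, sz, tids)
      alloc[alloc == 0L] <- 1L
      alloc <- pmin(alloc, setNames(sz, tids))
    }
    out <- lapply(tids[alloc > 0], function(tid) {
      ids <- corpus$post_id[corpus$thread_id == tid]
      take <- min(alloc[[tid]], length(ids))
      tibble(post_id = sort(sample(ids, take)), thread_id = tid)
    })
    bind_rows(out)
  })
}

# proportional allocation by largest remainder; ties broken by larger size,
# then by name for determinism. Quotas above thread size are capped and the
# slack re-distributed among threads with spare capacity.
largest_remainder <- function(n, sizes, ids) {
  quota <- n * sizes / sum(sizes)
  alloc <- floor(quota)
  rem <- quota - alloc
  short <- n - sum(alloc)
  ord <- order(-rem, -sizes, ids)
  i <- 1
  while (short > 0) {
    j <- ord[(i - 1) %% length(ord) + 1]
    if (alloc[j] < sizes[j]) {
      alloc[j] <- alloc[j] + 1
      short <- short - 1
    }
    i <- i + 1
    if (i > 10 * length(ord) + n) break # all threads saturated
  }
  alloc <- pmin(alloc, sizes)
  setNames(as.integer(alloc), ids)
}
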