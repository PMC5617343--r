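# Build small corpus tibbles in code. `make_corpus()` takes post rows and
# fills in preprocessing, so fixtures stay readable at the call site.

make_corpus <- function(post_id, thread_id, author_id, text,
                        timestamp = NULL, has_signature = 0) {
  n <- length(post_id)
  ts <- timestamp %||% (as.POSIXct("2014-03-01 12:00:00", tz = "UTC") + 60 * seq_len(n))
  df <- tibble::tibble(
    post_id = post_id, thread_id = thread_id, author_id = author_id,
    timestamp = ts, text = text,
    has_signature = rep_len(has_signature, n)
  )
  df$sentences <- lapply(df$text, preprocess_post)
  dplyr::arrange(df, thread_id, timestamp, post_id)
}

# tiny jsonl writer for read_corpus() tests
write_jsonl_posts <- function(path, rows) {
  lines <- vapply(rows, function(r) {
    jsonlite::toJSON(r, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path)
}

# random parameter set for the debate network (small sizes, for oracles)
random_debate_par <- function(d = 4, widths = c(2, 3), nf = 4, m = 3, J = 2,
                              V = 10) {
  um <- function(nr, nc, s = 0.5) matrix(runif(nr * nc, -s, s), nr, nc)
  h <- nf * length(widths)
  list(
    E = um(d, V + 1), widths = as.integer(widths),
    conv_W = lapply(widths, function(k) um(d * k, nf)),
    conv_b = lapply(widths, function(k) runif(nf, -0.1, 0.1)),
    A_H = um(h, h, 0.3), b_H = runif(h, -0.1, 0.1),
    A_T = um(h, h, 0.3), b_T = runif(h, -0.1, 0.1),
    Ui = um(m, h, 0.3), Uf = um(m, h, 0.3), Uo = um(m, h, 0.3), Ug = um(m, h, 0.3),
    Vi = um(m, m, 0.3), Vf = um(m, m, 0.3), Vo = um(m, m, 0.3), Vg = um(m, m, 0.3),
    bi = runif(m, -0.1, 0.1), bf = runif(m, -0.1, 0.1),
    bo = runif(m, -0.1, 0.1), bg = runif(m, -0.1, 0.1),
    Z = um(J, m, 0.4), bz = runif(J, -0.1, 0.1)
  )
}

# 20 trivially separable posts for the overfit checks: debate posts carry a
# disagreement phrase and a mention, non-debate posts are bland statements
separable_debate_threads <- function() {
  texts <- character(20)
  debate <- rep(c(TRUE, FALSE), 10)
  for (i in seq_len(20)) {
    texts[i] <- if (debate[i]) {
      "user1 i totally disagree with you! Laetrile is useless."
    } else {
      "Thanks for sharing the recipe. It was a lovely afternoon."
    }
  }
  corpus <- make_corpus(
    post_id = sprintf("s%02d", 1:20),
    thread_id = rep(sprintf("th%d", 1:4), each = 5),
    author_id = rep(c("user1", "user2"), 10),
    text = texts
  )
  labels <- tibble::tibble(
    post_id = sprintf("s%02d", 1:20),
    debate_label = ifelse(debate, "CAM_DEBATE", "NON_DEBATE"),
    stance_label = NA_character_
  )
  list(corpus = corpus, labels = labels)
}

separable_stance_posts <- function() {
  pro <- "It helped me so much, the gerson protocol works and i am grateful."
  con <- "Laetrile is snake oil, dangerous and useless, a total scam."
  is_pro <- rep(c(TRUE, FALSE), 10)
  corpus <- make_corpus(
    post_id = sprintf("q%02d", 1:20),
    thread_id = rep("tq", 20),
    author_id = rep(c("a", "b"), 10),
    text = ifelse(is_pro, pro, con)
  )
  labels <- tibble::tibble(
    post_id = sprintf("q%02d", 1:20),
    debate_label = "CAM_DEBATE",
    stance_label = ifelse(is_pro, "PRO_CAM", "CON_CAM")
  )
  list(corpus = corpus, labels = labels)
}

`%||%` <- rlang::`%||%`
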