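# Synthetic forum generator. Threads are sequences of background posts
# (topic-specific unigram text) interleaved with debate episodes: runs of
# at least two consecutive posts by two alternating authors holding
# opposite stances. With probability gamma a debate post carries overt
# interaction cues (a mention of the opponent's user name, agree/disagree
# phrasing, question/exclamation marks, topic keywords, stance-bearing
# words); with probability 1 - gamma it is plain background text and is
# identifiable only from its thread context. At gamma = 0 the labels are
# therefore statistically independent of post content, which is the
# ablation regime in which a sequence model's advantage must vanish.

PRO_LEXICON <- c("helped", "works", "healing", "recovered", "improving",
  "beneficial", "believer", "testimonial")
CON_LEXICON <- c("dangerous", "scam", "quack", "useless", "harmful",
  "debunked", "risky", "hoax", "snake", "oil")
BC_WORDS <- c("chemo", "tamoxifen", "radiation", "dcis", "biopsy",
  "oncologist", "surgery", "herceptin")
OTHER_WORDS <- c("moderator", "rules", "offtopic", "respect", "conduct",
  "behavior", "posting", "trolling")
CAM_EXTRA <- c("protocol", "detox", "juicing", "clinic", "dosage")

DISAGREE_PHRASES <- list(
  c("i", "disagree"), c("i", "don't", "agree"),
  c("i", "totally", "disagree"), c("that", "is", "not", "true")
)
CLOSING_PHRASE <- c("ok", "fair", "enough", "let's", "move", "on")

#' Configuration for the synthetic forum generator
#'
#' The defaults define the reference study conditions used throughout the
#' package's tests and benchmark: 200 threads of 6-20 posts, debate episode
#' rate `rho = 0.25` (the expected fraction of debate posts), episodes of
#' 2-5 posts, cue probability `gamma = 0.8`, and a 0.68 pro-CAM stance
#' mixture, mirroring the observed pro/con imbalance in real CAM debates.
#'
#' @param n_threads Number of threads.
#' @param posts_min,posts_max Posts-per-thread range (uniform).
#' @param n_authors Size of the author pool.
#' @param n_topics Number of background topics.
#' @param words_per_topic Topic-specific vocabulary size per topic.
#' @param rho Expected debate prevalence in `[0, 1]`.
#' @param episode_min,episode_max Debate episode length range
#'   (`episode_min >= 2`: a debate requires interaction).
#' @param gamma Context-dependence strength in `[0, 1]`: probability that a
#'   debate post carries overt cues.
#' @param type_mix Named probabilities over `CAM_DEBATE`, `BC_DEBATE`,
#'   `OTHER_DEBATE`.
#' @param pi_pro Probability that the episode initiator holds the pro-CAM
#'   stance (the opponent holds the other).
#' @param post_len_mean Mean background tokens per post.
#' @param seed Integer seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_threads = 200L, posts_min = 6L, posts_max = 20L,
                       n_authors = 40L, n_topics = 6L, words_per_topic = 30L,
                       rho = 0.25, episode_min = 2L, episode_max = 5L,
                       gamma = 0.8,
                       type_mix = c(CAM_DEBATE = 0.5, BC_DEBATE = 0.25,
                         OTHER_DEBATE = 0.25),
                       pi_pro = 0.68, post_len_mean = 22, seed = 7L) {
  if (posts_min > posts_max) abort("posts_min exceeds posts_max")
  if (episode_min > episode_max) abort("episode_min exceeds episode_max")
  if (episode_min < 2) abort("a debate episode needs at least 2 posts")
  for (p in c(rho, gamma, pi_pro)) {
    if (p < 0 || p > 1) abort("rates must lie in [0, 1]")
  }
  if (!setequal(names(type_mix), c("CAM_DEBATE", "BC_DEBATE", "OTHER_DEBATE"))) {
    abort("type_mix must name CAM_DEBATE, BC_DEBATE, OTHER_DEBATE")
  }
  structure(list(
    n_threads = as.integer(n_threads), posts_min = as.integer(posts_min),
    posts_max = as.integer(posts_max), n_authors = as.integer(n_authors),
    n_topics = as.integer(n_topics), words_per_topic = as.integer(words_per_topic),
    rho = rho, episode_min = as.integer(episode_min),
    episode_max = as.integer(episode_max), gamma = gamma,
    type_mix = type_mix / sum(type_mix), pi_pro = pi_pro,
    post_len_mean = post_len_mean, seed = as.integer(seed)
  ), class = "sim_config")
}

# Zipf-ish sampling weights
zipf_weights <- function(n) 1 / seq_len(n)

# uniform integer in [a, b]; safe when a == b (sample() would misread it)
rint <- function(a, b) if (a >= b) a else a + sample.int(b - a + 1L, 1L) - 1L

render_text <- function(tokens, enders) {
  # chunk tokens into sentences of ~8 words, capitalize, attach terminators
  n <- length(tokens)
  if (n == 0) return("")
  n_sent <- max(1L, round(n / 8))
  cut <- sort(c(0, sample(seq_len(max(n - 1, 1)), min(n_sent - 1, n - 1)), n))
  sents <- character(0)
  for (i in seq_len(length(cut) - 1)) {
    s <- tokens[(cut[i] + 1):cut[i + 1]]
    s[1] <- paste0(toupper(substr(s[1], 1, 1)), substr(s[1], 2, nchar(s[1])))
    ender <- if (length(enders) >= i && nzchar(enders[i])) enders[i] else "."
    sents <- c(sents, paste0(paste(s, collapse = " "), ender))
  }
  paste(sents, collapse = " ")
}

#' Generate a labeled synthetic forum corpus
#'
#' See [sim_config()] for the generative model. Timestamps are strictly
#' increasing within each thread; the same seed yields a bit-identical
#' corpus and labels.
#'
#' @param cfg A [sim_config()].
#' @return A list with elements `corpus` (a corpus tibble) and `labels`
#'   (tibble `post_id`, `debate_label`, `stance_label`).
#' @export
generate_corpus <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sim_config"))
  withr::with_seed(cfg$seed, {
    fw <- ts_lexicon("stopwords")
    topics <- lapply(seq_len(cfg$n_topics), function(t) {
      paste0("topic", t, "word", seq_len(cfg$words_per_topic))
    })
    authors <- paste0("user", seq_len(cfg$n_authors))
    signatures <- setNames(rbinom(cfg$n_authors, 1, 0.3), authors)
    type_words <- list(
      CAM_DEBATE = c(ts_lexicon("cam"), CAM_EXTRA),
      BC_DEBATE = BC_WORDS, OTHER_DEBATE = OTHER_WORDS
    )
    l_bar <- mean(seq(cfg$episode_min, cfg$episode_max))
    q_start <- if (cfg$rho >= 1) 1 else cfg$rho / ((1 - cfg$rho) * l_bar)

    bg_tokens <- function(n, topic) {
      n_fw <- rbinom(1, n, 0.5)
      toks <- c(
        sample(fw, n_fw, replace = TRUE, prob = zipf_weights(length(fw))),
        sample(topics[[topic]], n - n_fw, replace = TRUE,
          prob = zipf_weights(cfg$words_per_topic))
      )
      sample(toks)
    }

    rows <- list()
    labs <- list()
    pid <- 0L
    for (ti in seq_len(cfg$n_threads)) {
      tid <- sprintf("t%04d", ti)
      n_posts <- rint(cfg$posts_min, cfg$posts_max)
      topic <- sample(cfg$n_topics, 1)
      participants <- sample(authors, rint(3L, 6L))
      t0 <- as.POSIXct("2014-01-01 00:00:00", tz = "UTC") +
        ti * 86400 + round(runif(1, 0, 43200))
      gaps <- 60 + round(rexp(n_posts, 1 / 1800))
      times <- t0 + cumsum(gaps)

      # schedule debate episodes
      kind <- rep("BG", n_posts)
      type <- rep(NA_character_, n_posts)
      ep_id <- rep(0L, n_posts)
      ep_pos <- rep(0L, n_posts)
      ep_len <- rep(0L, n_posts)
      ep_author <- rep(NA_character_, n_posts)
      ep_stance <- rep(NA_character_, n_posts)
      pos <- 1L
      n_ep <- 0L
      while (pos <= n_posts) {
        if (pos <= n_posts - 1L && runif(1) < q_start) {
          len <- min(rint(cfg$episode_min, cfg$episode_max), n_posts - pos + 1L)
          n_ep <- n_ep + 1L
          ep_type <- sample(names(cfg$type_mix), 1, prob = cfg$type_mix)
          pair <- sample(participants, 2)
          init_pro <- runif(1) < cfg$pi_pro
          for (j in seq_len(len)) {
            i <- pos + j - 1L
            kind[i] <- "DEBATE"
            type[i] <- ep_type
            ep_id[i] <- n_ep
            ep_pos[i] <- j
            ep_len[i] <- len
            ep_author[i] <- pair[(j - 1) %% 2 + 1]
            is_init_author <- (j %% 2 == 1)
            ep_stance[i] <- if (xor(is_init_author, init_pro)) "CON_CAM" else "PRO_CAM"
          }
          pos <- pos + len
        } else {
          pos <- pos + 1L
        }
      }

      for (i in seq_len(n_posts)) {
        pid <- pid + 1L
        post_id <- sprintf("p%06d", pid)
        if (kind[i] == "BG") {
          author <- sample(participants, 1)
          n_tok <- max(5, rpois(1, cfg$post_len_mean))
          toks <- bg_tokens(n_tok, topic)
          # mild noise so cue features are imperfect on non-debate posts
          if (runif(1) < 0.05) {
            toks <- c(sample(setdiff(participants, author), 1), toks)
          }
          enders <- sample(c(".", "?"), 4, replace = TRUE, prob = c(0.92, 0.08))
          text <- render_text(toks, enders)
          debate_label <- "NON_DEBATE"
          stance_label <- NA_character_
        } else {
          author <- ep_author[i]
          opponent <- setdiff(ep_author[ep_id == ep_id[i]], author)[1]
          n_tok <- max(5, rpois(1, cfg$post_len_mean))
          toks <- bg_tokens(n_tok, topic)
          cue <- runif(1) < cfg$gamma
          if (cue) {
            tw <- sample(type_words[[type[i]]], rint(2L, 4L), replace = TRUE)
            extra <- tw
            if (type[i] == "CAM_DEBATE") {
              lex <- if (ep_stance[i] == "PRO_CAM") PRO_LEXICON else CON_LEXICON
              extra <- c(extra, sample(lex, rint(2L, 3L), replace = TRUE))
            }
            if (ep_pos[i] == 1L) {
              # initiation: assertive claim, no opponent yet
              toks <- c(extra, toks)
              enders <- c("!", sample(c(".", "?", "!"), 4, replace = TRUE))
            } else {
              phrase <- DISAGREE_PHRASES[[sample(length(DISAGREE_PHRASES), 1)]]
              toks <- c(opponent, phrase, extra, toks)
              enders <- c(sample(c("?", "!"), 1), sample(c(".", "?", "!"), 4,
                replace = TRUE, prob = c(0.6, 0.2, 0.2)))
            }
            if (ep_pos[i] == ep_len[i] && runif(1) < cfg$gamma) {
              toks <- c(toks, CLOSING_PHRASE) # debates wind down explicitly
            }
          } else {
            enders <- rep(".", 4)
          }
          text <- render_text(toks, enders)
          debate_label <- type[i]
          stance_label <- if (type[i] == "CAM_DEBATE") ep_stance[i] else NA_character_
        }
        rows[[pid]] <- tibble(
          post_id = post_id, thread_id = tid, author_id = author,
          timestamp = times[i], text = text,
          has_signature = unname(signatures[author])
        )
        labs[[pid]] <- tibble(post_id = post_id, debate_label = debate_label,
          stance_label = stance_label)
      }
    }
    corpus <- bind_rows(rows)
    corpus$sentences <- lapply(corpus$text, preprocess_post)
    corpus <- arrange(corpus, .data$thread_id, .data$timestamp, .data$post_id)
    list(corpus = as_tibble(corpus), labels = bind_rows(labs))
  })
}

#' Small frozen corpus for golden-file tests
#'
#' Six threads (about 40 posts) generated under a pinned configuration and
#' seed, guaranteed to contain at least one episode of each debate type.
#'
#' @return A list with `corpus` and `labels`, as [generate_corpus()].
#' @export
golden_fixture <- function() {
  gen <- generate_corpus(sim_config(
    n_threads = 6L, posts_min = 5L, posts_max = 9L, n_authors = 8L,
    n_topics = 3L, rho = 0.35, gamma = 1, episode_min = 2L, episode_max = 4L,
    type_mix = c(CAM_DEBATE = 1, BC_DEBATE = 1, OTHER_DEBATE = 1) / 3,
    seed = 20140101L
  ))
  types <- unique(gen$labels$debate_label)
  stopifnot(all(c("CAM_DEBATE", "BC_DEBATE", "OTHER_DEBATE") %in% types))
  gen
}
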