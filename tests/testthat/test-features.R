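test_that("thread_features counts posts, authors and mean length", {
  corpus <- make_corpus(
    post_id = c("p1", "p2", "p3"),
    thread_id = "t1",
    author_id = c("amy", "bob", "amy"),
    text = c("one two three four", "a b c d e f", "x y")
  )
  tf <- thread_features(corpus)
  expect_equal(tf$NumPost, 3)
  expect_equal(tf$NumUser, 2)
  expect_equal(tf$AvgLen, 4)

  single <- corpus[1, ]
  tf1 <- thread_features(single)
  expect_equal(unlist(tf1), c(NumPost = 1, NumUser = 1, AvgLen = 4))
  expect_error(thread_features(corpus[0, ]), "at least one post")
})

test_that("post_features applies the mention, sentiment and agreement rules", {
  thread <- make_corpus(
    post_id = c("p1", "p2"),
    thread_id = "t1",
    author_id = c("y", "x"),
    text = c("Hello there.", "X, I don't agree with Y")
  )
  # author of p2 is "x"; other participants: y (x's own name never counts)
  pf <- post_features(thread[2, ], thread[1, ], thread)
  expect_equal(pf$NumName, 1)
  expect_equal(pf$NAgree, 0)
  expect_equal(pf$NDisagree, 1) # negated agree counts as disagreement

  thread3 <- make_corpus(
    post_id = "p1", thread_id = "t", author_id = "z",
    text = "X, I don't agree with Y"
  )
  thread3_full <- thread3
  thread3_full$author_id <- "z"
  # participants {x, y, z}: simulate by adding silent posts from x and y
  thread3b <- make_corpus(
    post_id = c("p0", "p00", "p1"), thread_id = "t",
    author_id = c("x", "y", "z"),
    text = c("Hi.", "Hi.", "X, I don't agree with Y")
  )
  pf3 <- post_features(thread3b[3, ], thread3b[2, ], thread3b)
  expect_equal(pf3$NumName, 2)
})

test_that("sentiment, CAM and punctuation counts match the keyword lists", {
  thread <- make_corpus(
    post_id = c("p1", "p2"), thread_id = "t1", author_id = c("a", "b"),
    text = c("so happy and grateful!!", "gerson and laetrile supplement")
  )
  p1 <- post_features(thread[1, ], NULL, thread)
  expect_equal(p1$NumPos, 2)
  expect_equal(p1$`Num!`, 2)
  p2 <- post_features(thread[2, ], thread[1, ], thread)
  expect_equal(p2$NumCAM, 3)
  # morphological variants: frustrated -> frustrating
  thread2 <- make_corpus(
    post_id = "p1", thread_id = "t", author_id = "a",
    text = "This is frustrating and sad."
  )
  expect_equal(post_features(thread2[1, ], NULL, thread2)$NumNeg, 2)
})

test_that("NumOverlap is the stopword-free multiset intersection", {
  thread <- make_corpus(
    post_id = c("p1", "p2"), thread_id = "t1", author_id = c("a", "b"),
    text = c(
      "the gerson gerson protocol and the diet",
      "the gerson gerson gerson diet is the same"
    )
  )
  pf <- post_features(thread[2, ], thread[1, ], thread)
  # gerson: min(3, 2) = 2; diet: 1; "the"/"and"/"is"/"same" are stopwords or absent
  expect_equal(pf$NumOverlap, 3)
  expect_equal(post_features(thread[1, ], NULL, thread)$NumOverlap, 0)
})

test_that("TimeDif is seconds since previous post, clipped at 30 days", {
  t0 <- as.POSIXct("2014-01-01 00:00:00", tz = "UTC")
  thread <- make_corpus(
    post_id = c("p1", "p2", "p3"), thread_id = "t1",
    author_id = c("a", "b", "a"),
    text = rep("hello world", 3),
    timestamp = c(t0, t0 + 90, t0 + 90 + 120 * 86400)
  )
  expect_equal(post_features(thread[1, ], NULL, thread)$TimeDif, 0)
  expect_equal(post_features(thread[2, ], thread[1, ], thread)$TimeDif, 90)
  expect_equal(post_features(thread[3, ], thread[2, ], thread)$TimeDif, 30 * 86400)
})

test_that("count features are invariant to token order", {
  base <- c("gerson", "laetrile", "happy", "sad", "!", "?", "agree", "words")
  t1 <- paste(base, collapse = " ")
  t2 <- paste(rev(base), collapse = " ")
  th <- make_corpus(
    post_id = c("p1", "p2"), thread_id = "t", author_id = c("a", "b"),
    text = c(t1, t2)
  )
  f1 <- post_features(th[1, ], NULL, th)
  f2 <- post_features(th[2, ], NULL, th)
  for (col in c("NumNeg", "NumPos", "NumCAM", "Num?", "Num!", "NAgree", "NDisagree")) {
    expect_equal(f1[[col]], f2[[col]], info = col)
  }
})

test_that("CBOW embeddings have the right shape and are reproducible", {
  gen <- golden_fixture()
  emb <- train_cbow(gen$corpus, d = 8, iters = 3, seed = 5)
  expect_equal(nrow(emb), 8)
  expect_true(ncol(emb) > 50)
  expect_false(is.null(colnames(emb)))
  emb2 <- train_cbow(gen$corpus, d = 8, iters = 3, seed = 5)
  expect_identical(emb, emb2)
  expect_error(train_cbow(gen$corpus[0, ]), "empty")
})

test_that("CBOW places words with shared contexts closer together", {
  # "gerson" and "laetrile" appear in identical contexts; "zebra" does not
  n <- 120
  texts <- character(n)
  set.seed(2)
  for (i in seq_len(n)) {
    target <- if (i %% 2 == 0) "gerson" else "laetrile"
    texts[i] <- paste("the", target, "therapy discussion thread number", sample(5, 1))
  }
  texts[1:20] <- paste(texts[1:20], "zebra sighting unrelated footnote")
  corpus <- make_corpus(
    post_id = sprintf("p%03d", 1:n), thread_id = "t", author_id = "a",
    text = texts
  )
  emb <- train_cbow(corpus, d = 12, iters = 25, seed = 4)
  sim_pair <- cosine_similarity(emb[, "gerson"], emb[, "laetrile"])
  sim_rand <- cosine_similarity(emb[, "gerson"], emb[, "zebra"])
  expect_gt(sim_pair, sim_rand)
})

test_that("LDA rows are normalized, reproducible, and separate disjoint topics", {
  half1 <- paste("apple banana cherry date", collapse = " ")
  half2 <- paste("quark lepton boson photon", collapse = " ")
  corpus <- make_corpus(
    post_id = sprintf("p%02d", 1:40),
    thread_id = "t", author_id = "a",
    text = rep(c(half1, half2), 20)
  )
  lda <- train_lda(corpus, k = 2, iters = 80, seed = 3)
  expect_equal(rowSums(lda$phi), c(1, 1), tolerance = 1e-9)
  lda2 <- train_lda(corpus, k = 2, iters = 80, seed = 3)
  expect_identical(lda$phi, lda2$phi)
  top <- top_topic_words(lda, n = 4)
  w1 <- top$word[top$topic == 1]
  w2 <- top$word[top$topic == 2]
  fruit <- c("apple", "banana", "cherry", "date")
  expect_true(all(w1 %in% fruit) || all(w2 %in% fruit))
  expect_error(train_lda(corpus, k = 0), "at least 1")
})

test_that("lexical features give self-similarity 1 and first-post similarity 0", {
  gen <- golden_fixture()
  corpus <- gen$corpus
  lda <- train_lda(corpus, k = 5, iters = 50, seed = 2)
  emb <- train_cbow(corpus, d = 8, iters = 5, seed = 2)
  same <- lexical_features(corpus[3, ], corpus[3, ], lda, emb)
  expect_equal(same$lda_sim, 1, tolerance = 1e-6)
  expect_equal(same$w2v_sim, 1, tolerance = 1e-6)
  first <- lexical_features(corpus[1, ], NULL, lda, emb)
  expect_equal(first$lda_sim, 0)
  expect_equal(first$w2v_sim, 0)
  # topic block is a probability vector
  expect_equal(sum(as.numeric(same[paste0("lda_", 1:5)])), 1, tolerance = 1e-9)
})

test_that("cosine of the feature vectors matches a direct computation", {
  gen <- golden_fixture()
  corpus <- gen$corpus
  emb <- train_cbow(corpus, d = 8, iters = 5, seed = 2)
  v1 <- threadstance:::mean_embedding(unlist(corpus$sentences[[2]]), emb)
  v2 <- threadstance:::mean_embedding(unlist(corpus$sentences[[1]]), emb)
  lf <- lexical_features(corpus[2, ], corpus[1, ], NULL, emb)
  expect_equal(lf$w2v_sim, sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2))),
    tolerance = 1e-12)
})

test_that("feature_matrix covers every post and does not mutate the corpus", {
  gen <- golden_fixture()
  before <- gen$corpus
  fm <- feature_matrix(gen$corpus)
  expect_equal(fm$post_id, gen$corpus$post_id)
  expect_true(all(c("NumPost", "NumName", "TimeDif", "NDisagree") %in% names(fm)))
  expect_identical(gen$corpus, before)
})
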