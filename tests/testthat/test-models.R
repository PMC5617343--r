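small_debate_cfg <- function(epochs = 40L, ...) {
  debate_config(task = "binary", d = 8L, n_filters = 4L, m = 8L,
    epochs = epochs, lr = 0.02, optimizer = "momentum", cbow_iters = 5L,
    seed = 2L, ...)
}

test_that("the debate model overfits a separable toy problem", {
  toy <- separable_debate_threads()
  model <- suppressWarnings(train_debate_model(toy$corpus, toy$labels, small_debate_cfg()))
  expect_lt(utils::tail(model$loss_trace, 1), model$loss_trace[1])
  pred <- predict_debate(model, toy$corpus)
  gold <- to_binary_debate(toy$labels$debate_label[match(pred$post_id, toy$labels$post_id)])
  expect_gte(mean(pred$label == gold), 0.95)
})

test_that("debate training is deterministic under a fixed seed", {
  toy <- separable_debate_threads()
  cfg <- small_debate_cfg(epochs = 5L)
  m1 <- train_debate_model(toy$corpus, toy$labels, cfg)
  m2 <- train_debate_model(toy$corpus, toy$labels, cfg)
  expect_identical(m1$loss_trace, m2$loss_trace)
  expect_identical(m1$par$Z, m2$par$Z)
})

test_that("predict_debate keeps thread order, ties to NON_DEBATE", {
  toy <- separable_debate_threads()
  cfg <- small_debate_cfg(epochs = 2L)
  model <- train_debate_model(toy$corpus, toy$labels, cfg)
  one <- toy$corpus[toy$corpus$thread_id == "th1", ][1, ]
  p1 <- predict_debate(model, one)
  expect_equal(nrow(p1), 1)
  expect_equal(predict_debate(model, toy$corpus[0, ]) |> nrow(), 0)
  # zeroed softmax parameters give exact ties -> conservative class
  model$par$Z[] <- 0
  model$par$bz[] <- 0
  pt <- predict_debate(model, toy$corpus)
  expect_true(all(pt$label == "NON_DEBATE"))
  expect_equal(pt$p_NON_DEBATE, rep(0.5, nrow(pt)))
})

test_that("reversing a thread changes debate predictions in general", {
  gen <- generate_corpus(sim_config(n_threads = 16, seed = 5))
  cfg <- small_debate_cfg(epochs = 15L)
  model <- train_debate_model(gen$corpus, gen$labels, cfg)
  th <- gen$corpus[gen$corpus$thread_id == gen$corpus$thread_id[1], ]
  fwd <- predict_debate(model, th)
  rev_th <- th[rev(seq_len(nrow(th))), ]
  rev_th$timestamp <- th$timestamp # keep sort order reversed via post order
  # predict on the reversed sequence by rebuilding thread order
  rev_th$post_id <- th$post_id
  bwd <- predict_debate(model, rev_th)
  probs_fwd <- fwd$p_DEBATE
  probs_bwd <- bwd$p_DEBATE[match(fwd$post_id, bwd$post_id)]
  expect_gt(max(abs(probs_fwd - rev(probs_bwd)), na.rm = TRUE), 0)
})

test_that("threads without labels are skipped with a warning", {
  toy <- separable_debate_threads()
  labels <- toy$labels
  labels$debate_label[labels$post_id %in%
    toy$corpus$post_id[toy$corpus$thread_id == "th1"]] <- NA
  labels <- labels[!is.na(labels$debate_label), ]
  expect_warning(
    train_debate_model(toy$corpus, labels, small_debate_cfg(epochs = 1L)),
    "no labeled post"
  )
  expect_error(
    train_debate_model(toy$corpus, labels[0, ], small_debate_cfg(epochs = 1L)),
    "no labeled posts"
  )
})

test_that("the 4-class model trains and predicts over the typed label set", {
  gen <- golden_fixture()
  cfg <- debate_config(task = "four_class", d = 8L, n_filters = 4L, m = 8L,
    epochs = 10L, lr = 0.02, optimizer = "momentum", cbow_iters = 5L, seed = 3L)
  model <- train_debate_model(gen$corpus, gen$labels, cfg)
  expect_equal(model$classes, debate_classes())
  pred <- predict_debate(model, gen$corpus)
  expect_true(all(pred$label %in% debate_classes()))
  expect_equal(rowSums(as.matrix(pred[paste0("p_", debate_classes())])),
    rep(1, nrow(pred)), tolerance = 1e-9)
})

test_that("neural checkpoints round-trip with bit-identical predictions", {
  toy <- separable_debate_threads()
  model <- train_debate_model(toy$corpus, toy$labels, small_debate_cfg(epochs = 3L))
  path <- withr::local_tempfile(fileext = ".json")
  save_model(model, path)
  back <- load_model(path)
  p1 <- predict_debate(model, toy$corpus)
  p2 <- predict_debate(back, toy$corpus)
  expect_identical(p1$p_DEBATE, p2$p_DEBATE)
  expect_identical(p1$label, p2$label)
})

test_that("the stance CNN overfits a separable toy set deterministically", {
  toy <- separable_stance_posts()
  cfg <- stance_config(d = 8L, n_filters = 4L, epochs = 30L, lr = 0.02,
    optimizer = "momentum", cbow_iters = 5L, seed = 2L)
  model <- train_stance_model(toy$corpus, toy$labels, cfg)
  pred <- predict_stance(model, toy$corpus)
  gold <- toy$labels$stance_label[match(pred$post_id, toy$labels$post_id)]
  expect_gte(mean(pred$label == gold), 0.95)
  expect_setequal(unique(pred$label), stance_classes())
  m2 <- train_stance_model(toy$corpus, toy$labels, cfg)
  expect_identical(model$loss_trace, m2$loss_trace)
  # missing labels are an error
  bad <- toy$labels
  bad$stance_label[1] <- NA
  expect_error(train_stance_model(toy$corpus, bad, cfg), "stance label")
})

test_that("stance ties resolve to PRO_CAM and OOV-only posts are handled", {
  toy <- separable_stance_posts()
  cfg <- stance_config(d = 8L, n_filters = 4L, epochs = 1L, cbow_iters = 3L, seed = 1L)
  model <- train_stance_model(toy$corpus, toy$labels, cfg)
  model$par$Z[] <- 0
  model$par$bz[] <- 0
  oov_post <- make_corpus("z1", "tz", "a", "qqqq wwww eeee rrrr")
  pr <- predict_stance(model, oov_post)
  expect_equal(pr$label, "PRO_CAM")
  expect_equal(pr$p_PRO_CAM, 0.5)
})

test_that("lasso baseline: penalty limit, separable fit and majority rule", {
  set.seed(9)
  n <- 60
  x1 <- c(rnorm(n / 2, -3), rnorm(n / 2, 3))
  x2 <- rnorm(n)
  feats <- tibble::tibble(post_id = as.character(1:n), f1 = x1, f2 = x2)
  y <- rep(c("NON_DEBATE", "DEBATE"), each = n / 2)

  inf_fit <- train_lr_baseline(feats, y, lambda = 1e6)
  cf <- tidy(inf_fit)
  expect_true(all(cf$estimate[cf$term != "(Intercept)"] == 0))
  # intercept-only model predicts the majority class everywhere
  y_imb <- c(rep("NON_DEBATE", 40), rep("DEBATE", 20))
  maj_fit <- train_lr_baseline(feats, y_imb, lambda = 1e6)
  expect_true(all(predict_lr(maj_fit, feats)$label == "NON_DEBATE"))

  sep_fit <- train_lr_baseline(feats, y, lambda = 1e-4)
  expect_equal(mean(predict_lr(sep_fit, feats)$label == y), 1)
  expect_error(train_lr_baseline(feats, rep("DEBATE", n)), "constant")
})

test_that("lasso coefficients match a proximal-gradient oracle", {
  # small dense problem; oracle minimizes the same objective as glmnet:
  # (1/n) * logistic deviance / 2-style NLL + lambda * ||beta||_1
  set.seed(10)
  n <- 10; p <- 3
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  beta_true <- c(1.5, -2, 0)
  pr <- 1 / (1 + exp(-(X %*% beta_true)))
  y <- ifelse(runif(n) < pr, "B", "A")
  if (length(unique(y)) < 2) y[1] <- setdiff(c("A", "B"), y[1])
  feats <- tibble::as_tibble(as.data.frame(X))
  lam <- 0.05
  fit <- train_lr_baseline(feats, y, lambda = lam, classes = c("A", "B"))

  # oracle: proximal gradient (ISTA) on the identical standardized design,
  # minimizing -(1/n) loglik + lam * sum(abs(beta))
  Xs <- scale(X) # same z-scoring as train_lr_baseline
  yy <- as.numeric(y == "B")
  b0 <- 0; b <- rep(0, p)
  step <- 0.5
  soft <- function(z, t) sign(z) * pmax(abs(z) - t, 0)
  for (it in 1:100000) {
    mu <- 1 / (1 + exp(-(b0 + Xs %*% b)))
    b0 <- b0 - step * mean(mu - yy)
    b <- soft(b - step * as.vector(t(Xs) %*% (mu - yy)) / n, step * lam)
  }
  cf <- tidy(fit)
  est <- cf$estimate[match(paste0("f", 1:p), cf$term)]
  expect_equal(unname(est), unname(b), tolerance = 1e-4)
})

test_that("lr predictions carry calibrated two-class probabilities", {
  set.seed(11)
  feats <- tibble::tibble(f1 = rnorm(40), f2 = rnorm(40))
  y <- ifelse(feats$f1 > 0, "DEBATE", "NON_DEBATE")
  fit <- train_lr_baseline(feats, y, lambda = 0.01)
  pr <- predict_lr(fit, feats)
  expect_equal(pr$p_DEBATE + pr$p_NON_DEBATE, rep(1, 40), tolerance = 1e-12)
  expect_true(all(pr$label %in% c("DEBATE", "NON_DEBATE")))
})

test_that("tidy and glance summarize fitted models", {
  toy <- separable_debate_threads()
  model <- train_debate_model(toy$corpus, toy$labels, small_debate_cfg(epochs = 2L))
  td <- tidy(model)
  expect_true(all(c("group", "n_parameters", "l2_norm") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$task, "binary")
  expect_true(gl$n_parameters > 0)
  p <- autoplot(model)
  expect_s3_class(p, "ggplot")
})
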