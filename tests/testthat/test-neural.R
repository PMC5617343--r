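# Reference-path tests of the numeric building blocks, each against an
# independent brute-force computation.

brute_conv <- function(W, H, b) {
  d <- nrow(W); l <- ncol(W); k <- ncol(H)
  out <- numeric(l - k + 1)
  for (i in seq_len(l - k + 1)) {
    s <- 0
    for (r in seq_len(d)) for (c in seq_len(k)) s <- s + W[r, i + c - 1] * H[r, c]
    out[i] <- tanh(s + b)
  }
  out
}

test_that("conv_feature_map implements the Frobenius-product convolution", {
  W <- matrix(c(1, 2, 3), 1, 3)
  expect_equal(conv_feature_map(W, matrix(1, 1, 1), 0), tanh(c(1, 2, 3)))
  expect_equal(conv_feature_map(W, matrix(0, 1, 2), 0), c(0, 0))
  set.seed(1)
  for (rep in 1:20) {
    W <- matrix(rnorm(15), 3, 5)
    H <- matrix(rnorm(6), 3, 2)
    b <- rnorm(1)
    expect_equal(conv_feature_map(W, H, b), brute_conv(W, H, b), tolerance = 1e-10)
  }
  expect_error(conv_feature_map(matrix(0, 3, 1), matrix(0, 3, 2)), "shorter")
  expect_error(conv_feature_map(matrix(0, 3, 5), matrix(0, 2, 2)), "dimension")
})

test_that("max_over_time pools the maximum", {
  expect_equal(max_over_time(c(0.2, -0.5, 0.9)), 0.9)
  expect_equal(max_over_time(0.3), 0.3)
  set.seed(2)
  f <- rnorm(20)
  expect_equal(max_over_time(f), sort(f)[length(f)])
  expect_error(max_over_time(numeric(0)), "empty")
})

test_that("encode_post pads, handles OOV and returns one value per filter", {
  emb <- matrix(rnorm(5 * 3), 5, 3, dimnames = list(NULL, c("a", "b", "c")))
  bank <- new_filter_bank(5, widths = 2:5, n_per_width = 100, seed = 1)
  expect_length(bank, 400) # reference bank size
  v <- encode_post(c("a", "zzz"), emb, bank)
  expect_length(v, 400)
  expect_true(all(is.finite(v)))
  expect_true(all(v >= -1 & v <= 1))
  # single token with k_max = 5: padding makes every width applicable
  v1 <- encode_post("a", emb, bank)
  expect_true(all(is.finite(v1)))
  # all-zero bank gives the zero vector
  zero_bank <- lapply(bank[1:8], function(f) list(H = 0 * f$H, b = 0))
  expect_equal(encode_post(c("a", "b"), emb, zero_bank), rep(0, 8))
  expect_error(encode_post("a", emb, list()), "empty")
})

test_that("highway mixes transform and carry paths as gated", {
  set.seed(3)
  h <- 6
  l <- rnorm(h)
  A_H <- matrix(rnorm(h * h), h, h); b_H <- rnorm(h)
  A_T <- matrix(0, h, h)
  # carry limit: gate forced closed returns the input unchanged
  expect_equal(highway(l, A_H, b_H, A_T, rep(-1e6, h)), l)
  # transform limit: gate forced open returns g(A_H l + b_H)
  expect_equal(highway(l, A_H, b_H, A_T, rep(1e6, h)),
    tanh(as.vector(A_H %*% l) + b_H))
  # random parameters against an elementwise scalar oracle
  A_T <- matrix(rnorm(h * h), h, h); b_T <- rnorm(h)
  z <- highway(l, A_H, b_H, A_T, b_T)
  oracle <- numeric(h)
  for (i in seq_len(h)) {
    t_i <- 1 / (1 + exp(-(sum(A_T[i, ] * l) + b_T[i])))
    oracle[i] <- t_i * tanh(sum(A_H[i, ] * l) + b_H[i]) + (1 - t_i) * l[i]
  }
  expect_equal(z, oracle, tolerance = 1e-10)
  expect_error(highway(l, A_H[, 1:3], b_H, A_T, b_T), "dimensions")
})

test_that("lstm_step reproduces the gated recurrence", {
  zero <- function(m, h) list(
    Ui = matrix(0, m, h), Uf = matrix(0, m, h), Uo = matrix(0, m, h), Ug = matrix(0, m, h),
    Vi = matrix(0, m, m), Vf = matrix(0, m, m), Vo = matrix(0, m, m), Vg = matrix(0, m, m),
    bi = rep(0, m), bf = rep(0, m), bo = rep(0, m), bg = rep(0, m)
  )
  st <- lstm_step(rep(1, 4), list(h = rep(0, 2), c = rep(0, 2)), zero(2, 4))
  expect_equal(st$h, c(0, 0))
  expect_equal(st$c, c(0, 0))

  # hand-worked scalar step: U = V = 1, b = 0, x = 0, h = 0, c = 1
  p1 <- lapply(zero(1, 1), function(x) x + 1)
  p1$bi <- p1$bf <- p1$bo <- p1$bg <- 0
  st1 <- lstm_step(0, list(h = 0, c = 1), p1)
  expect_equal(st1$c, 0.5, tolerance = 1e-10)          # sigma(0)*1 + sigma(0)*tanh(0)
  expect_equal(st1$h, 0.5 * tanh(0.5), tolerance = 1e-10) # ~0.2311
  expect_equal(round(st1$h, 4), 0.2311)

  # random small instance against a scalar-loop oracle
  set.seed(4)
  m <- 3; hx <- 5
  p <- list(
    Ui = matrix(rnorm(m * hx), m, hx), Uf = matrix(rnorm(m * hx), m, hx),
    Uo = matrix(rnorm(m * hx), m, hx), Ug = matrix(rnorm(m * hx), m, hx),
    Vi = matrix(rnorm(m * m), m, m), Vf = matrix(rnorm(m * m), m, m),
    Vo = matrix(rnorm(m * m), m, m), Vg = matrix(rnorm(m * m), m, m),
    bi = rnorm(m), bf = rnorm(m), bo = rnorm(m), bg = rnorm(m)
  )
  x <- rnorm(hx); h0 <- rnorm(m); c0 <- rnorm(m)
  st <- lstm_step(x, list(h = h0, c = c0), p)
  sig <- function(v) 1 / (1 + exp(-v))
  for (i in seq_len(m)) {
    ii <- sig(sum(p$Ui[i, ] * x) + sum(p$Vi[i, ] * h0) + p$bi[i])
    ff <- sig(sum(p$Uf[i, ] * x) + sum(p$Vf[i, ] * h0) + p$bf[i])
    oo <- sig(sum(p$Uo[i, ] * x) + sum(p$Vo[i, ] * h0) + p$bo[i])
    gg <- tanh(sum(p$Ug[i, ] * x) + sum(p$Vg[i, ] * h0) + p$bg[i])
    cc <- ff * c0[i] + ii * gg
    expect_equal(st$c[i], cc, tolerance = 1e-10)
    expect_equal(st$h[i], oo * tanh(cc), tolerance = 1e-10)
  }
  bad <- p; bad$Ui <- bad$Ui[, 1:2]
  expect_error(lstm_step(x, list(h = h0, c = c0), bad), "inconsistent")
})

test_that("label_distribution is a stable softmax", {
  expect_equal(label_distribution(rep(0, 3), matrix(0, 4, 3), rep(0, 4)),
    rep(0.25, 4))
  Z <- matrix(c(1, 1), 2, 1)
  expect_equal(label_distribution(1, Z, c(0, 0)), c(0.5, 0.5))
  # huge logits must not overflow
  p <- label_distribution(1, matrix(c(1000, 0), 2, 1), c(0, 0))
  expect_true(all(is.finite(p)))
  expect_equal(p[1], 1, tolerance = 1e-10)
  expect_equal(sum(p), 1, tolerance = 1e-12)
})

test_that("sequence_nll sums clipped per-step log losses", {
  expect_equal(sequence_nll(list(c(1, 0), c(0, 1)), c(1, 2)), 0)
  expect_equal(sequence_nll(list(c(0.5, 0.5), c(0.5, 0.5)), c(1, 2)),
    2 * log(2), tolerance = 1e-12)
  set.seed(5)
  probs <- lapply(1:6, function(i) {
    p <- runif(3); p / sum(p)
  })
  y <- sample(3, 6, replace = TRUE)
  expect_equal(sequence_nll(probs, y),
    -sum(vapply(1:6, function(t) log(probs[[t]][y[t]]), numeric(1))),
    tolerance = 1e-12)
  expect_gte(sequence_nll(probs, y), 0)
  # clipping keeps the value finite
  expect_true(is.finite(sequence_nll(list(c(0, 1)), 1L)))
  expect_error(sequence_nll(list(c(1, 0)), c(1, 2)), "length")
})

test_that("the compiled thread forward equals the composed R primitives", {
  set.seed(6)
  for (rep in 1:5) {
    par <- random_debate_par()
    posts <- lapply(seq_len(sample(2:4, 1)), function(i) sample(1:11, sample(1:7, 1), replace = TRUE))
    y <- sample(1:2, length(posts), replace = TRUE)
    res <- threadstance:::cpp_debate_thread(posts, as.integer(y), par, FALSE)
    ref <- threadstance:::r_debate_forward(posts, par)
    expect_equal(max(abs(res$probs - ref)), 0, tolerance = 1e-10)
    expect_equal(rowSums(res$probs), rep(1, length(posts)), tolerance = 1e-9)
  }
})

test_that("the compiled stance forward equals the composed R primitives", {
  set.seed(7)
  par <- random_debate_par()
  spar <- par[c("E", "widths", "conv_W", "conv_b")]
  h <- 8
  spar$Z <- matrix(runif(2 * h, -0.4, 0.4), 2, h)
  spar$bz <- runif(2, -0.1, 0.1)
  for (rep in 1:5) {
    toks <- sample(1:11, sample(1:6, 1), replace = TRUE)
    res <- threadstance:::cpp_stance_post(as.integer(toks), 1L, spar, FALSE)
    ref <- threadstance:::r_stance_forward(toks, spar)
    expect_equal(max(abs(as.vector(res$probs) - ref)), 0, tolerance = 1e-10)
  }
})
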