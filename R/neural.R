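# Reference (float64, pure R) implementations of the numeric building
# blocks of the neural classifiers: the convolutional feature map with
# max-over-time pooling, the highway layer, the LSTM step, the softmax
# label distribution and the sequence negative log-likelihood. The training
# path (src/nnet.cpp) implements the same operations with analytic
# gradients; tests hold the two routes together to 1e-10.

#' Convolutional feature map of a post matrix
#'
#' `f[i] = tanh(<W[, i:(i+k-1)], H> + b)` where `<A, B>` is the Frobenius
#' inner product, `W` is the `d x l` matrix of word embeddings of a post and
#' `H` a `d x k` filter.
#'
#' @param W A `d x l` numeric matrix (one column per token).
#' @param H A `d x k` filter matrix.
#' @param b Scalar bias.
#' @return A numeric vector of length `l - k + 1`, entries in (-1, 1).
#' @export
conv_feature_map <- function(W, H, b = 0) {
  d <- nrow(W)
  l <- ncol(W)
  k <- ncol(H)
  if (nrow(H) != d) abort("filter and post matrix disagree on embedding dimension")
  if (l < k) abort("post is shorter than the filter width (apply padding first)")
  f <- vapply(seq_len(l - k + 1), function(i) {
    sum(W[, i:(i + k - 1), drop = FALSE] * H) + b
  }, numeric(1))
  tanh(f)
}

#' Max-over-time pooling
#'
#' @param f A non-empty numeric feature map.
#' @return Its maximum entry.
#' @export
max_over_time <- function(f) {
  if (length(f) == 0) abort("cannot pool an empty feature map")
  max(f)
}

#' Create a bank of convolution filters
#'
#' @param d Embedding dimensionality.
#' @param widths Filter widths (default 2:5).
#' @param n_per_width Filters per width (default 100, giving `h = 400`).
#' @param scale Half-width of the uniform initialization.
#' @param seed Integer seed.
#' @return An object of class `filter_bank`: a list of filters, each a list
#'   with elements `H` (`d x k` matrix) and `b` (scalar).
#' @export
new_filter_bank <- function(d, widths = 2:5, n_per_width = 100L,
                            scale = NULL, seed = 1L) {
  if (length(widths) == 0 || n_per_width < 1) abort("filter bank must be non-empty")
  withr::with_seed(seed, {
    bank <- list()
    for (k in widths) {
      sc <- scale %||% sqrt(1 / (d * k))
      for (r in seq_len(n_per_width)) {
        bank[[length(bank) + 1]] <- list(
          H = matrix(runif(d * k, -sc, sc), d, k),
          b = 0
        )
      }
    }
    structure(bank, class = "filter_bank", d = d, widths = widths)
  })
}

#' Encode a post as a fixed-length vector
#'
#' Looks up token embeddings (out-of-vocabulary tokens map to the `oov`
#' vector), zero-pads the post up to the maximum filter width, and takes
#' the max-over-time pooled convolution for every filter of the bank.
#'
#' @param tokens A character vector of tokens (may be empty).
#' @param emb A `d x |V|` embedding matrix with word column names.
#' @param bank A [new_filter_bank()] object.
#' @param oov Embedding used for unknown tokens (default: zero vector).
#' @return A numeric vector of length `h = length(bank)`, entries in
#'   \[-1, 1\].
#' @export
encode_post <- function(tokens, emb, bank, oov = NULL) {
  if (length(bank) == 0) abort("filter bank is empty")
  d <- nrow(emb)
  oov <- oov %||% rep(0, d)
  k_max <- max(vapply(bank, function(f) ncol(f$H), 1L))
  l <- max(length(tokens), k_max)
  W <- matrix(0, d, l)
  if (length(tokens) > 0) {
    idx <- match(tokens, colnames(emb))
    for (j in seq_along(tokens)) {
      W[, j] <- if (is.na(idx[j])) oov else emb[, idx[j]]
    }
  }
  vapply(bank, function(f) max_over_time(conv_feature_map(W, f$H, f$b)), numeric(1))
}

#' Highway layer
#'
#' `z = t * g(A_H l + b_H) + (1 - t) * l` with transform gate
#' `t = sigmoid(A_T l + b_T)`; the complement `1 - t` is the carry gate.
#'
#' @param l Input vector (length `h`).
#' @param A_H,b_H Affine transform parameters (`h x h`, `h`).
#' @param A_T,b_T Affine gate parameters.
#' @param g Elementwise activation of the transform branch (default tanh).
#' @return A numeric vector of length `h`.
#' @export
highway <- function(l, A_H, b_H, A_T, b_T, g = tanh) {
  h <- length(l)
  if (!all(dim(A_H) == c(h, h)) || !all(dim(A_T) == c(h, h)) ||
    length(b_H) != h || length(b_T) != h) {
    abort("highway parameter dimensions do not match the input")
  }
  t_gate <- sigmoid(as.vector(A_T %*% l) + b_T)
  t_gate * g(as.vector(A_H %*% l) + b_H) + (1 - t_gate) * l
}

#' One LSTM step
#'
#' Standard LSTM recurrence with input, forget and output gates:
#' `i = sigmoid(Ui x + Vi h + bi)` (and analogously `f`, `o`),
#' `g = tanh(Ug x + Vg h + bg)`, `c' = f * c + i * g`, `h' = o * tanh(c')`.
#'
#' @param x Input vector (length `h`, the highway output).
#' @param state List with `h` and `c`, each of length `m` (zeros at `t = 0`).
#' @param params List with matrices `Ui,Uf,Uo,Ug` (`m x h`), `Vi,Vf,Vo,Vg`
#'   (`m x m`) and vectors `bi,bf,bo,bg` (length `m`).
#' @return A list with the new `h` and `c`.
#' @export
lstm_step <- function(x, state, params) {
  m <- length(state$h)
  for (nm in c("Ui", "Uf", "Uo", "Ug")) {
    if (nrow(params[[nm]]) != m || ncol(params[[nm]]) != length(x)) {
      abort(paste0("LSTM parameter ", nm, " has inconsistent shape"))
    }
  }
  gate <- function(U, V, b) as.vector(U %*% x) + as.vector(V %*% state$h) + b
  i <- sigmoid(gate(params$Ui, params$Vi, params$bi))
  f <- sigmoid(gate(params$Uf, params$Vf, params$bf))
  o <- sigmoid(gate(params$Uo, params$Vo, params$bo))
  g <- tanh(gate(params$Ug, params$Vg, params$bg))
  c_new <- f * state$c + i * g
  list(h = o * tanh(c_new), c = c_new)
}

#' Softmax label distribution
#'
#' `Pr(j) = exp(h . z_j + b_j) / sum_j' exp(h . z_j' + b_j')`, computed with
#' max-subtraction for numerical stability.
#'
#' @param h Hidden vector (length `m`).
#' @param Z A `|J| x m` matrix of per-label parameter vectors.
#' @param b Length-`|J|` bias vector.
#' @return A probability vector over the labels (sums to 1).
#' @export
label_distribution <- function(h, Z, b) {
  if (ncol(Z) != length(h) || nrow(Z) != length(b)) {
    abort("softmax parameter dimensions do not match")
  }
  softmax_stable(as.vector(Z %*% h) + b)
}

#' Negative log-likelihood of a label sequence
#'
#' `L = -sum_t log Pr(y_t)`, with probabilities clipped at 1e-12 so the
#' value stays finite.
#'
#' @param prob_seq List of probability vectors, one per post.
#' @param labels Integer vector of true label indices (same length).
#' @return A non-negative number.
#' @export
sequence_nll <- function(prob_seq, labels) {
  if (length(prob_seq) != length(labels)) {
    abort("probability sequence and label sequence differ in length")
  }
  -sum(vapply(seq_along(labels), function(t) {
    log(max(prob_seq[[t]][labels[t]], 1e-12))
  }, numeric(1)))
}

# Full reference forward pass over one thread: returns the T x |J| matrix of
# per-post label distributions, composing the exported primitives. Used as
# the independent route against the compiled training path.
r_debate_forward <- function(posts_idx, par) {
  d <- nrow(par$E)
  widths <- par$widths
  k_max <- max(widths)
  # unpack stacked filters into a plain bank
  bank <- list()
  for (wi in seq_along(widths)) {
    k <- widths[wi]
    Wk <- par$conv_W[[wi]]
    for (r in seq_len(ncol(Wk))) {
      bank[[length(bank) + 1]] <- list(H = matrix(Wk[, r], d, k), b = par$conv_b[[wi]][r])
    }
  }
  m <- length(par$bi)
  state <- list(h = rep(0, m), c = rep(0, m))
  probs <- matrix(0, length(posts_idx), nrow(par$Z))
  for (t in seq_along(posts_idx)) {
    idx <- posts_idx[[t]]
    l <- max(length(idx), k_max)
    W <- matrix(0, d, l)
    if (length(idx) > 0) W[, seq_along(idx)] <- par$E[, idx, drop = FALSE]
    lp <- vapply(bank, function(f) max_over_time(conv_feature_map(W, f$H, f$b)), numeric(1))
    z <- highway(lp, par$A_H, par$b_H, par$A_T, par$b_T)
    state <- lstm_step(z, state, par)
    probs[t, ] <- label_distribution(state$h, par$Z, par$bz)
  }
  probs
}

# Reference forward for the stance CNN (no highway, no LSTM).
r_stance_forward <- function(idx, par) {
  d <- nrow(par$E)
  widths <- par$widths
  k_max <- max(widths)
  bank <- list()
  for (wi in seq_along(widths)) {
    k <- widths[wi]
    Wk <- par$conv_W[[wi]]
    for (r in seq_len(ncol(Wk))) {
      bank[[length(bank) + 1]] <- list(H = matrix(Wk[, r], d, k), b = par$conv_b[[wi]][r])
    }
  }
  l <- max(length(idx), k_max)
  W <- matrix(0, d, l)
  if (length(idx) > 0) W[, seq_along(idx)] <- par$E[, idx, drop = FALSE]
  lp <- vapply(bank, function(f) max_over_time(conv_feature_map(W, f$H, f$b)), numeric(1))
  softmax_stable(as.vector(par$Z %*% lp) + par$bz)
}
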