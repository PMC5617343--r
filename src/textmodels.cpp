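// Lexical models used by the engineered-feature baseline and for word
// vector initialization: CBOW embeddings with negative sampling and a
// collapsed Gibbs sampler for latent Dirichlet allocation. Both draw all
// randomness from R's RNG, so runs are reproducible under set.seed().

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;
}

// CBOW with negative sampling. sents: list of 1-based token index vectors.
// Returns a dim x V embedding matrix (the input vectors).
// [[Rcpp::export]]
arma::mat cpp_cbow_train(List sents, int V, int dim, int window, int negative,
                         int iters, double alpha0) {
  const int S = sents.size();
  std::vector<std::vector<int>> sv(S);
  std::vector<double> freq(V, 0.0);
  long long total_words = 0;
  for (int s = 0; s < S; ++s) {
    IntegerVector x = sents[s];
    sv[s].assign(x.begin(), x.end());
    for (int w : sv[s]) freq[w - 1] += 1.0;
    total_words += sv[s].size();
  }
  // unigram^0.75 table for negative sampling, via cumulative distribution
  std::vector<double> cum(V);
  double acc = 0.0;
  for (int v = 0; v < V; ++v) {
    acc += std::pow(freq[v], 0.75);
    cum[v] = acc;
  }
  arma::mat syn0(V, dim), syn1(V, dim, arma::fill::zeros);
  for (int v = 0; v < V; ++v)
    for (int j = 0; j < dim; ++j) syn0(v, j) = (unif_rand() - 0.5) / dim;

  const double total_steps = (double)iters * (double)total_words;
  double step = 0.0;
  arma::rowvec neu1(dim), neu1e(dim);
  for (int it = 0; it < iters; ++it) {
    for (int s = 0; s < S; ++s) {
      const std::vector<int>& sent = sv[s];
      const int L = (int)sent.size();
      for (int pos = 0; pos < L; ++pos) {
        const double lr =
            std::max(alpha0 * (1.0 - step / (total_steps + 1.0)), alpha0 * 1e-4);
        step += 1.0;
        const int red = runif_int(window); // dynamic window reduction
        const int win = window - red;
        neu1.zeros();
        int cn = 0;
        for (int a = pos - win; a <= pos + win; ++a) {
          if (a == pos || a < 0 || a >= L) continue;
          neu1 += syn0.row(sent[a] - 1);
          ++cn;
        }
        if (cn == 0) continue;
        neu1 /= (double)cn;
        neu1e.zeros();
        const int wtrue = sent[pos] - 1;
        for (int d = 0; d <= negative; ++d) {
          int target;
          double label;
          if (d == 0) {
            target = wtrue;
            label = 1.0;
          } else {
            const double u = unif_rand() * acc;
            target = (int)(std::lower_bound(cum.begin(), cum.end(), u) - cum.begin());
            if (target >= V) target = V - 1;
            if (target == wtrue) continue;
            label = 0.0;
          }
          const double f = arma::dot(neu1, syn1.row(target));
          const double g = (label - 1.0 / (1.0 + std::exp(-f))) * lr;
          neu1e += g * syn1.row(target);
          syn1.row(target) += g * neu1;
        }
        for (int a = pos - win; a <= pos + win; ++a) {
          if (a == pos || a < 0 || a >= L) continue;
          syn0.row(sent[a] - 1) += neu1e;
        }
      }
    }
  }
  return syn0.t();
}

// Collapsed Gibbs sampler for LDA. docs: list of 1-based token index
// vectors. Returns the K x V topic-word matrix phi with rows
// (n_kw + beta) / (n_k + V beta).
// [[Rcpp::export]]
arma::mat cpp_lda_train(List docs, int V, int K, double alpha, double beta,
                        int iters) {
  const int D = docs.size();
  std::vector<std::vector<int>> dv(D);
  long long N = 0;
  for (int d = 0; d < D; ++d) {
    IntegerVector x = docs[d];
    dv[d].assign(x.begin(), x.end());
    N += dv[d].size();
  }
  arma::imat nkw(K, V, arma::fill::zeros);
  arma::ivec nk(K, arma::fill::zeros);
  arma::imat ndk(D, K, arma::fill::zeros);
  std::vector<std::vector<int>> z(D);
  for (int d = 0; d < D; ++d) {
    z[d].resize(dv[d].size());
    for (size_t i = 0; i < dv[d].size(); ++i) {
      const int k = runif_int(K);
      z[d][i] = k;
      nkw(k, dv[d][i] - 1) += 1;
      nk[k] += 1;
      ndk(d, k) += 1;
    }
  }
  std::vector<double> p(K);
  const double Vbeta = V * beta;
  for (int it = 0; it < iters; ++it) {
    for (int d = 0; d < D; ++d) {
      for (size_t i = 0; i < dv[d].size(); ++i) {
        const int w = dv[d][i] - 1;
        const int old = z[d][i];
        nkw(old, w) -= 1;
        nk[old] -= 1;
        ndk(d, old) -= 1;
        double tot = 0.0;
        for (int k = 0; k < K; ++k) {
          tot += (nkw(k, w) + beta) / (nk[k] + Vbeta) * (ndk(d, k) + alpha);
          p[k] = tot;
        }
        const double u = unif_rand() * tot;
        int knew = 0;
        while (knew < K - 1 && p[knew] < u) ++knew;
        z[d][i] = knew;
        nkw(knew, w) += 1;
        nk[knew] += 1;
        ndk(d, knew) += 1;
      }
    }
  }
  arma::mat phi(K, V);
  for (int k = 0; k < K; ++k)
    for (int v = 0; v < V; ++v) phi(k, v) = (nkw(k, v) + beta) / (nk[k] + Vbeta);
  return phi;
}

// Fold-in inference for one document at fixed phi.
// [[Rcpp::export]]
arma::vec cpp_lda_infer(IntegerVector doc, arma::mat phi, double alpha,
                        int iters) {
  const int K = phi.n_rows;
  const int n = doc.size();
  std::vector<int> z(n);
  arma::vec ndk(K, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    const int k = runif_int(K);
    z[i] = k;
    ndk[k] += 1.0;
  }
  std::vector<double> p(K);
  for (int it = 0; it < iters; ++it) {
    for (int i = 0; i < n; ++i) {
      const int w = doc[i] - 1;
      ndk[z[i]] -= 1.0;
      double tot = 0.0;
      for (int k = 0; k < K; ++k) {
        tot += phi(k, w) * (ndk[k] + alpha);
        p[k] = tot;
      }
      const double u = unif_rand() * tot;
      int knew = 0;
      while (knew < K - 1 && p[knew] < u) ++knew;
      z[i] = knew;
      ndk[knew] += 1.0;
    }
  }
  return (ndk + alpha) / (n + K * alpha);
}
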