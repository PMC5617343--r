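// Training path of the neural classifiers: forward pass and analytic
// gradients for (a) the CNN -> highway -> LSTM -> softmax sequence model
// over the posts of one thread and (b) the CNN -> softmax post classifier.
// Float64 throughout; the pure-R primitives in R/neural.R are the
// reference route these functions are tested against.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::vec sigv(const arma::vec& x) { return 1.0 / (1.0 + arma::exp(-x)); }

struct ConvCache {
  std::vector<arma::mat> X;     // per width: (d*k) x P patch matrix
  std::vector<arma::uvec> amax; // per width: argmax position per filter
  arma::vec lvec;               // pooled tanh values, length h
  int l;                        // padded post length
};

static void conv_forward(const std::vector<int>& toks, const arma::mat& E,
                         const std::vector<int>& widths,
                         const std::vector<arma::mat>& cW,
                         const std::vector<arma::vec>& cb, ConvCache& cc) {
  const int d = E.n_rows;
  const int kmax = *std::max_element(widths.begin(), widths.end());
  const int l = std::max((int)toks.size(), kmax);
  arma::mat W(d, l, arma::fill::zeros);
  for (size_t j = 0; j < toks.size(); ++j) W.col(j) = E.col(toks[j] - 1);
  int h = 0;
  for (const auto& m : cW) h += m.n_cols;
  cc.lvec.set_size(h);
  cc.X.clear();
  cc.amax.clear();
  cc.l = l;
  int off = 0;
  for (size_t wi = 0; wi < widths.size(); ++wi) {
    const int k = widths[wi];
    const int P = l - k + 1;
    arma::mat X(d * k, P);
    for (int p = 0; p < P; ++p) X.col(p) = arma::vectorise(W.cols(p, p + k - 1));
    arma::mat M = cW[wi].t() * X; // n_k x P
    M.each_col() += cb[wi];
    M = arma::tanh(M);
    arma::uvec am(M.n_rows);
    for (arma::uword r = 0; r < M.n_rows; ++r) {
      arma::uword a;
      const double v = M.row(r).max(a);
      am[r] = a;
      cc.lvec[off + r] = v;
    }
    cc.X.push_back(std::move(X));
    cc.amax.push_back(std::move(am));
    off += M.n_rows;
  }
}

static void conv_backward(const std::vector<int>& toks, const ConvCache& cc,
                          const std::vector<int>& widths,
                          const std::vector<arma::mat>& cW, const arma::vec& dl,
                          std::vector<arma::mat>& gW, std::vector<arma::vec>& gb,
                          arma::mat& gE) {
  const int d = gE.n_rows;
  arma::mat dWpost(d, cc.l, arma::fill::zeros);
  int off = 0;
  for (size_t wi = 0; wi < widths.size(); ++wi) {
    const int k = widths[wi];
    const int nk = cW[wi].n_cols;
    for (int r = 0; r < nk; ++r) {
      const double pooled = cc.lvec[off + r];
      const double g = dl[off + r] * (1.0 - pooled * pooled);
      if (g == 0.0) continue;
      const arma::uword p = cc.amax[wi][r];
      gW[wi].col(r) += g * cc.X[wi].col(p);
      gb[wi][r] += g;
      for (int kk = 0; kk < k; ++kk)
        dWpost.col(p + kk) += g * cW[wi].col(r).subvec((arma::uword)kk * d, (arma::uword)(kk + 1) * d - 1);
    }
    off += nk;
  }
  for (size_t j = 0; j < toks.size(); ++j) gE.col(toks[j] - 1) += dWpost.col(j);
}

static std::vector<int> as_std_ivec(const IntegerVector& v) {
  return std::vector<int>(v.begin(), v.end());
}

// Sequence model over one thread. posts: list of 1-based token index
// vectors (index ncol(E) is the learned OOV vector). y: 1-based label per
// post, 0 for unlabeled posts (no loss contribution). Returns loss, the
// T x |J| probability matrix, and (optionally) gradients of every
// parameter group.
// [[Rcpp::export]]
List cpp_debate_thread(List posts, IntegerVector y, List par, bool want_grad) {
  arma::mat E = par["E"];
  IntegerVector widthsR = par["widths"];
  std::vector<int> widths = as_std_ivec(widthsR);
  List cWl = par["conv_W"], cbl = par["conv_b"];
  std::vector<arma::mat> cW;
  std::vector<arma::vec> cb;
  for (int i = 0; i < cWl.size(); ++i) {
    cW.push_back(as<arma::mat>(cWl[i]));
    cb.push_back(as<arma::vec>(cbl[i]));
  }
  arma::mat A_H = par["A_H"], A_T = par["A_T"];
  arma::vec b_H = par["b_H"], b_T = par["b_T"];
  arma::mat Ui = par["Ui"], Uf = par["Uf"], Uo = par["Uo"], Ug = par["Ug"];
  arma::mat Vi = par["Vi"], Vf = par["Vf"], Vo = par["Vo"], Vg = par["Vg"];
  arma::vec bi = par["bi"], bf = par["bf"], bo = par["bo"], bg = par["bg"];
  arma::mat Z = par["Z"];
  arma::vec bz = par["bz"];

  const int T = posts.size();
  const int m = bi.n_elem;
  const int J = bz.n_elem;

  std::vector<std::vector<int>> toks(T);
  for (int t = 0; t < T; ++t) toks[t] = as_std_ivec(posts[t]);

  std::vector<ConvCache> cc(T);
  arma::mat tg(0, 0), hv(0, 0), zs(0, 0);
  arma::mat gi(m, T), gf(m, T), go(m, T), gg(m, T), cs(m, T), hs(m, T);
  const int h = [&] { int s = 0; for (auto& w : cW) s += w.n_cols; return s; }();
  tg.set_size(h, T);
  hv.set_size(h, T);
  zs.set_size(h, T);
  arma::mat probs(T, J);
  arma::vec hprev(m, arma::fill::zeros), cprev(m, arma::fill::zeros);
  double loss = 0.0;

  for (int t = 0; t < T; ++t) {
    conv_forward(toks[t], E, widths, cW, cb, cc[t]);
    const arma::vec& lv = cc[t].lvec;
    arma::vec tgt = sigv(A_T * lv + b_T);
    arma::vec hvt = arma::tanh(A_H * lv + b_H);
    arma::vec zt = tgt % hvt + (1.0 - tgt) % lv;
    tg.col(t) = tgt;
    hv.col(t) = hvt;
    zs.col(t) = zt;
    arma::vec it = sigv(Ui * zt + Vi * hprev + bi);
    arma::vec ft = sigv(Uf * zt + Vf * hprev + bf);
    arma::vec ot = sigv(Uo * zt + Vo * hprev + bo);
    arma::vec gt = arma::tanh(Ug * zt + Vg * hprev + bg);
    arma::vec ct = ft % cprev + it % gt;
    arma::vec ht = ot % arma::tanh(ct);
    gi.col(t) = it; gf.col(t) = ft; go.col(t) = ot; gg.col(t) = gt;
    cs.col(t) = ct; hs.col(t) = ht;
    arma::vec logits = Z * ht + bz;
    logits -= logits.max();
    arma::vec ex = arma::exp(logits);
    arma::vec pr = ex / arma::accu(ex);
    probs.row(t) = pr.t();
    if (y[t] > 0) loss -= std::log(std::max(pr[y[t] - 1], 1e-12));
    hprev = ht;
    cprev = ct;
  }

  List out = List::create(Named("loss") = loss, Named("probs") = probs);
  if (!want_grad) return out;

  arma::mat gE(arma::size(E), arma::fill::zeros);
  std::vector<arma::mat> gcW;
  std::vector<arma::vec> gcb;
  for (size_t i = 0; i < cW.size(); ++i) {
    gcW.push_back(arma::mat(arma::size(cW[i]), arma::fill::zeros));
    gcb.push_back(arma::vec(arma::size(cb[i]), arma::fill::zeros));
  }
  arma::mat gA_H(arma::size(A_H), arma::fill::zeros), gA_T(arma::size(A_T), arma::fill::zeros);
  arma::vec gb_H(h, arma::fill::zeros), gb_T(h, arma::fill::zeros);
  arma::mat gUi(arma::size(Ui), arma::fill::zeros), gUf(arma::size(Uf), arma::fill::zeros),
      gUo(arma::size(Uo), arma::fill::zeros), gUg(arma::size(Ug), arma::fill::zeros);
  arma::mat gVi(arma::size(Vi), arma::fill::zeros), gVf(arma::size(Vf), arma::fill::zeros),
      gVo(arma::size(Vo), arma::fill::zeros), gVg(arma::size(Vg), arma::fill::zeros);
  arma::vec gbi(m, arma::fill::zeros), gbf(m, arma::fill::zeros),
      gbo(m, arma::fill::zeros), gbg(m, arma::fill::zeros);
  arma::mat gZ(arma::size(Z), arma::fill::zeros);
  arma::vec gbz(J, arma::fill::zeros);

  arma::vec dh_next(m, arma::fill::zeros), dc_next(m, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    arma::vec dlogit = probs.row(t).t();
    if (y[t] > 0) {
      dlogit[y[t] - 1] -= 1.0;
    } else {
      dlogit.zeros();
    }
    const arma::vec ht = hs.col(t);
    gZ += dlogit * ht.t();
    gbz += dlogit;
    arma::vec dh = Z.t() * dlogit + dh_next;
    const arma::vec ct = cs.col(t);
    const arma::vec tc = arma::tanh(ct);
    const arma::vec it = gi.col(t), ft = gf.col(t), ot = go.col(t), gt = gg.col(t);
    arma::vec do_ = dh % tc;
    arma::vec dc = dh % ot % (1.0 - tc % tc) + dc_next;
    const arma::vec c_prev = (t > 0) ? arma::vec(cs.col(t - 1)) : arma::vec(m, arma::fill::zeros);
    const arma::vec h_prev = (t > 0) ? arma::vec(hs.col(t - 1)) : arma::vec(m, arma::fill::zeros);
    arma::vec df = dc % c_prev;
    arma::vec di = dc % gt;
    arma::vec dgp = dc % it;
    dc_next = dc % ft;
    arma::vec dai = di % it % (1.0 - it);
    arma::vec daf = df % ft % (1.0 - ft);
    arma::vec dao = do_ % ot % (1.0 - ot);
    arma::vec dag = dgp % (1.0 - gt % gt);
    const arma::vec zt = zs.col(t);
    gUi += dai * zt.t(); gUf += daf * zt.t(); gUo += dao * zt.t(); gUg += dag * zt.t();
    gVi += dai * h_prev.t(); gVf += daf * h_prev.t(); gVo += dao * h_prev.t(); gVg += dag * h_prev.t();
    gbi += dai; gbf += daf; gbo += dao; gbg += dag;
    arma::vec dz = Ui.t() * dai + Uf.t() * daf + Uo.t() * dao + Ug.t() * dag;
    dh_next = Vi.t() * dai + Vf.t() * daf + Vo.t() * dao + Vg.t() * dag;
    // highway backward
    const arma::vec tgt = tg.col(t), hvt = hv.col(t), lv = cc[t].lvec;
    arma::vec dtg = dz % (hvt - lv);
    arma::vec dhv = dz % tgt;
    arma::vec dl = dz % (1.0 - tgt);
    arma::vec daT = dtg % tgt % (1.0 - tgt);
    arma::vec daH = dhv % (1.0 - hvt % hvt);
    gA_T += daT * lv.t();
    gb_T += daT;
    gA_H += daH * lv.t();
    gb_H += daH;
    dl += A_T.t() * daT + A_H.t() * daH;
    conv_backward(toks[t], cc[t], widths, cW, dl, gcW, gcb, gE);
  }

  List gconv_W(gcW.size()), gconv_b(gcb.size());
  for (size_t i = 0; i < gcW.size(); ++i) {
    gconv_W[i] = gcW[i];
    gconv_b[i] = gcb[i];
  }
  out["grad"] = List::create(
      Named("E") = gE, Named("conv_W") = gconv_W, Named("conv_b") = gconv_b,
      Named("A_H") = gA_H, Named("b_H") = gb_H, Named("A_T") = gA_T, Named("b_T") = gb_T,
      Named("Ui") = gUi, Named("Uf") = gUf, Named("Uo") = gUo, Named("Ug") = gUg,
      Named("Vi") = gVi, Named("Vf") = gVf, Named("Vo") = gVo, Named("Vg") = gVg,
      Named("bi") = gbi, Named("bf") = gbf, Named("bo") = gbo, Named("bg") = gbg,
      Named("Z") = gZ, Named("bz") = gbz);
  return out;
}

// CNN post classifier (stance): conv encoder + softmax over the pooled
// post vector. Same conventions as cpp_debate_thread.
// [[Rcpp::export]]
List cpp_stance_post(IntegerVector tokens, int y, List par, bool want_grad) {
  arma::mat E = par["E"];
  IntegerVector widthsR = par["widths"];
  std::vector<int> widths = as_std_ivec(widthsR);
  List cWl = par["conv_W"], cbl = par["conv_b"];
  std::vector<arma::mat> cW;
  std::vector<arma::vec> cb;
  for (int i = 0; i < cWl.size(); ++i) {
    cW.push_back(as<arma::mat>(cWl[i]));
    cb.push_back(as<arma::vec>(cbl[i]));
  }
  arma::mat Z = par["Z"];
  arma::vec bz = par["bz"];

  std::vector<int> toks = as_std_ivec(tokens);
  ConvCache cc;
  conv_forward(toks, E, widths, cW, cb, cc);
  arma::vec logits = Z * cc.lvec + bz;
  logits -= logits.max();
  arma::vec ex = arma::exp(logits);
  arma::vec pr = ex / arma::accu(ex);
  double loss = (y > 0) ? -std::log(std::max(pr[y - 1], 1e-12)) : 0.0;
  List out = List::create(Named("loss") = loss, Named("probs") = pr);
  if (!want_grad) return out;

  arma::vec dlogit = pr;
  if (y > 0) dlogit[y - 1] -= 1.0; else dlogit.zeros();
  arma::mat gZ = dlogit * cc.lvec.t();
  arma::vec gbz = dlogit;
  arma::vec dl = Z.t() * dlogit;
  arma::mat gE(arma::size(E), arma::fill::zeros);
  std::vector<arma::mat> gcW;
  std::vector<arma::vec> gcb;
  for (size_t i = 0; i < cW.size(); ++i) {
    gcW.push_back(arma::mat(arma::size(cW[i]), arma::fill::zeros));
    gcb.push_back(arma::vec(arma::size(cb[i]), arma::fill::zeros));
  }
  conv_backward(toks, cc, widths, cW, dl, gcW, gcb, gE);
  List gconv_W(gcW.size()), gconv_b(gcb.size());
  for (size_t i = 0; i < gcW.size(); ++i) {
    gconv_W[i] = gcW[i];
    gconv_b[i] = gcb[i];
  }
  out["grad"] = List::create(Named("E") = gE, Named("conv_W") = gconv_W,
                             Named("conv_b") = gconv_b, Named("Z") = gZ,
                             Named("bz") = gbz);
  return out;
}
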