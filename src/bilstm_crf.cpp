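// Character-level BiLSTM-CRF sequence tagger: training (BPTT through a
// bidirectional LSTM encoder plus exact CRF forward-backward gradients) and
// Viterbi decoding.  Matrix conventions: embeddings E are V x D (row per
// vocabulary character); LSTM input-to-hidden weights are 4H x D with gate
// order (input, forget, candidate, output); emissions are built as k x n
// internally and exposed to R as n x k; the transition matrix A is
// (k+2) x (k+2) with START = k and STOP = k+1 (0-based).

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static inline double lse(const arma::vec& v) {
  double m = v.max();
  return m + std::log(arma::accu(arma::exp(v - m)));
}

struct TaggerParams {
  arma::mat E, Wxf, Whf, Wxb, Whb, Wo, A;
  arma::vec bf, bb, bo;
};

static TaggerParams params_from_list(const List& p) {
  TaggerParams q;
  q.E = as<arma::mat>(p["E"]);
  q.Wxf = as<arma::mat>(p["Wxf"]); q.Whf = as<arma::mat>(p["Whf"]);
  q.bf = as<arma::vec>(p["bf"]);
  q.Wxb = as<arma::mat>(p["Wxb"]); q.Whb = as<arma::mat>(p["Whb"]);
  q.bb = as<arma::vec>(p["bb"]);
  q.Wo = as<arma::mat>(p["Wo"]); q.bo = as<arma::vec>(p["bo"]);
  q.A = as<arma::mat>(p["A"]);
  return q;
}

static List params_to_list(const TaggerParams& q) {
  return List::create(
    Named("E") = q.E, Named("Wxf") = q.Wxf, Named("Whf") = q.Whf,
    Named("bf") = q.bf, Named("Wxb") = q.Wxb, Named("Whb") = q.Whb,
    Named("bb") = q.bb, Named("Wo") = q.Wo, Named("bo") = q.bo,
    Named("A") = q.A);
}

// One direction of the LSTM encoder; caches everything BPTT needs.
struct LstmCache {
  arma::mat I, F, G, O, C, TC, H;  // all Hdim x n
};

static void lstm_forward(const arma::mat& Wx, const arma::mat& Wh,
                         const arma::vec& b, const arma::mat& X,
                         bool reverse, LstmCache& cc) {
  const arma::uword Hn = Wh.n_cols, n = X.n_cols;
  cc.I.set_size(Hn, n); cc.F.set_size(Hn, n); cc.G.set_size(Hn, n);
  cc.O.set_size(Hn, n); cc.C.set_size(Hn, n); cc.TC.set_size(Hn, n);
  cc.H.set_size(Hn, n);
  arma::vec h(Hn, arma::fill::zeros), c(Hn, arma::fill::zeros);
  for (arma::uword s = 0; s < n; ++s) {
    arma::uword t = reverse ? (n - 1 - s) : s;
    arma::vec z = Wx * X.col(t) + Wh * h + b;
    arma::vec i = 1.0 / (1.0 + arma::exp(-z.subvec(0, Hn - 1)));
    arma::vec f = 1.0 / (1.0 + arma::exp(-z.subvec(Hn, 2 * Hn - 1)));
    arma::vec g = arma::tanh(z.subvec(2 * Hn, 3 * Hn - 1));
    arma::vec o = 1.0 / (1.0 + arma::exp(-z.subvec(3 * Hn, 4 * Hn - 1)));
    c = f % c + i % g;
    arma::vec tc = arma::tanh(c);
    h = o % tc;
    cc.I.col(t) = i; cc.F.col(t) = f; cc.G.col(t) = g; cc.O.col(t) = o;
    cc.C.col(t) = c; cc.TC.col(t) = tc; cc.H.col(t) = h;
  }
}

// BPTT for one direction.  dH is the gradient wrt this direction's hidden
// states; accumulates parameter gradients and returns dX contribution.
static void lstm_backward(const arma::mat& Wx, const arma::mat& Wh,
                          const arma::mat& X, bool reverse,
                          const LstmCache& cc, const arma::mat& dH,
                          arma::mat& dWx, arma::mat& dWh, arma::vec& db,
                          arma::mat& dX) {
  const arma::uword Hn = Wh.n_cols, n = X.n_cols;
  arma::vec dh_next(Hn, arma::fill::zeros), dc_next(Hn, arma::fill::zeros);
  for (arma::uword s = 0; s < n; ++s) {
    // walk time in the direction opposite to the forward pass
    arma::uword t = reverse ? s : (n - 1 - s);
    arma::vec dh = dH.col(t) + dh_next;
    arma::vec tc = cc.TC.col(t);
    arma::vec dov = dh % tc;
    arma::vec dc = dh % cc.O.col(t) % (1.0 - tc % tc) + dc_next;
    arma::vec c_prev(Hn, arma::fill::zeros);
    arma::vec h_prev(Hn, arma::fill::zeros);
    if (reverse) {
      if (t + 1 < n) { c_prev = cc.C.col(t + 1); h_prev = cc.H.col(t + 1); }
    } else {
      if (t > 0) { c_prev = cc.C.col(t - 1); h_prev = cc.H.col(t - 1); }
    }
    arma::vec i = cc.I.col(t), f = cc.F.col(t), g = cc.G.col(t),
      o = cc.O.col(t);
    arma::vec dz(4 * Hn);
    dz.subvec(0, Hn - 1) = dc % g % i % (1.0 - i);
    dz.subvec(Hn, 2 * Hn - 1) = dc % c_prev % f % (1.0 - f);
    dz.subvec(2 * Hn, 3 * Hn - 1) = dc % i % (1.0 - g % g);
    dz.subvec(3 * Hn, 4 * Hn - 1) = dov % o % (1.0 - o);
    dWx += dz * X.col(t).t();
    dWh += dz * h_prev.t();
    db += dz;
    dX.col(t) += Wx.t() * dz;
    dh_next = Wh.t() * dz;
    dc_next = dc % f;
  }
}

// Emission matrix (k x n) for one sequence; H_out optionally receives the
// (possibly dropped-out) concatenated hidden states used to compute it.
static arma::mat emissions_for(const TaggerParams& q, const arma::uvec& x,
                               LstmCache& cf, LstmCache& cb,
                               arma::mat& Hcat) {
  const arma::uword n = x.n_elem;
  arma::mat X(q.E.n_cols, n);
  for (arma::uword t = 0; t < n; ++t) X.col(t) = q.E.row(x[t]).t();
  lstm_forward(q.Wxf, q.Whf, q.bf, X, false, cf);
  lstm_forward(q.Wxb, q.Whb, q.bb, X, true, cb);
  Hcat = arma::join_cols(cf.H, cb.H);
  arma::mat P = q.Wo * Hcat;
  P.each_col() += q.bo;
  return P;
}

// CRF negative log-likelihood and gradients wrt P (k x n) and A for one
// sequence with gold labels y (0-based, < k).
static double crf_nll_grad(const arma::mat& P, const arma::mat& A,
                           const arma::uvec& y, arma::mat& dP,
                           arma::mat& dA) {
  const arma::uword k = P.n_rows, n = P.n_cols;
  const arma::uword START = k, STOP = k + 1;
  arma::mat Ak = A.submat(0, 0, k - 1, k - 1);
  arma::mat alpha(k, n), beta(k, n);
  alpha.col(0) = A.row(START).cols(0, k - 1).t() + P.col(0);
  for (arma::uword t = 1; t < n; ++t) {
    for (arma::uword j = 0; j < k; ++j) {
      alpha(j, t) = lse(alpha.col(t - 1) + Ak.col(j)) + P(j, t);
    }
  }
  arma::vec a_stop = A.col(STOP).head(k);
  double logZ = lse(alpha.col(n - 1) + a_stop);
  beta.col(n - 1) = a_stop;
  for (arma::uword s = 1; s < n; ++s) {
    arma::uword t = n - 1 - s;
    arma::vec nxt = beta.col(t + 1) + P.col(t + 1);
    for (arma::uword i = 0; i < k; ++i) {
      beta(i, t) = lse(Ak.row(i).t() + nxt);
    }
  }
  // node marginals -> dP; pairwise marginals -> dA
  dP = arma::exp(alpha + beta - logZ);
  for (arma::uword t = 0; t + 1 < n; ++t) {
    arma::vec nxt = beta.col(t + 1) + P.col(t + 1);
    arma::mat xi = arma::exp(arma::repmat(alpha.col(t), 1, k) + Ak +
                             arma::repmat(nxt.t(), k, 1) - logZ);
    dA.submat(0, 0, k - 1, k - 1) += xi;
  }
  for (arma::uword j = 0; j < k; ++j) {
    dA(START, j) += dP(j, 0);
    dA(j, STOP) += dP(j, n - 1);
  }
  // subtract gold feature counts; accumulate gold score
  double gold = A(START, y[0]) + P(y[0], 0);
  dP(y[0], 0) -= 1.0;
  dA(START, y[0]) -= 1.0;
  for (arma::uword t = 1; t < n; ++t) {
    gold += A(y[t - 1], y[t]) + P(y[t], t);
    dP(y[t], t) -= 1.0;
    dA(y[t - 1], y[t]) -= 1.0;
  }
  gold += A(y[n - 1], STOP);
  dA(y[n - 1], STOP) -= 1.0;
  return logZ - gold;
}

static arma::uvec viterbi_path(const arma::mat& P, const arma::mat& A) {
  const arma::uword k = P.n_rows, n = P.n_cols;
  const arma::uword START = k, STOP = k + 1;
  arma::mat Ak = A.submat(0, 0, k - 1, k - 1);
  arma::vec delta = A.row(START).cols(0, k - 1).t() + P.col(0);
  arma::umat back(k, n, arma::fill::zeros);
  for (arma::uword t = 1; t < n; ++t) {
    arma::vec nd(k);
    for (arma::uword j = 0; j < k; ++j) {
      arma::vec cand = delta + Ak.col(j);
      arma::uword bi = cand.index_max();   // first (smallest) index on ties
      back(j, t) = bi;
      nd(j) = cand(bi) + P(j, t);
    }
    delta = nd;
  }
  arma::vec fin = delta + A.col(STOP).head(k);
  arma::uvec path(n);
  path[n - 1] = fin.index_max();
  for (arma::uword s = 1; s < n; ++s) {
    arma::uword t = n - 1 - s;
    path[t] = back(path[t + 1], t + 1);
  }
  return path;
}

struct Grads {
  TaggerParams g;
  explicit Grads(const TaggerParams& q) {
    g.E = arma::zeros(arma::size(q.E));
    g.Wxf = arma::zeros(arma::size(q.Wxf));
    g.Whf = arma::zeros(arma::size(q.Whf));
    g.bf = arma::zeros(arma::size(q.bf));
    g.Wxb = arma::zeros(arma::size(q.Wxb));
    g.Whb = arma::zeros(arma::size(q.Whb));
    g.bb = arma::zeros(arma::size(q.bb));
    g.Wo = arma::zeros(arma::size(q.Wo));
    g.bo = arma::zeros(arma::size(q.bo));
    g.A = arma::zeros(arma::size(q.A));
  }
};

// Accumulate the gradient of one sequence's NLL into gr; returns the NLL.
static double sequence_grad(const TaggerParams& q, const arma::uvec& x,
                            const arma::uvec& y, double keep_prob,
                            std::mt19937& rng, Grads& gr) {
  const arma::uword n = x.n_elem, Hn = q.Whf.n_cols;
  LstmCache cf, cb;
  arma::mat Hcat;
  arma::mat P = emissions_for(q, x, cf, cb, Hcat);
  arma::mat M(2 * Hn, n, arma::fill::ones);
  if (keep_prob < 1.0) {
    std::bernoulli_distribution bern(keep_prob);
    for (arma::uword j = 0; j < M.n_elem; ++j) {
      M[j] = bern(rng) ? (1.0 / keep_prob) : 0.0;
    }
    arma::mat Hd = Hcat % M;
    P = q.Wo * Hd;
    P.each_col() += q.bo;
    Hcat = Hd;  // emissions were computed from the dropped-out states
  }
  arma::mat dP, dA(arma::size(q.A), arma::fill::zeros);
  double nll = crf_nll_grad(P, q.A, y, dP, dA);
  gr.g.A += dA;
  gr.g.Wo += dP * Hcat.t();
  gr.g.bo += arma::sum(dP, 1);
  arma::mat dHd = q.Wo.t() * dP;
  arma::mat dH = (keep_prob < 1.0) ? arma::mat(dHd % M) : dHd;
  arma::mat X(q.E.n_cols, n);
  for (arma::uword t = 0; t < n; ++t) X.col(t) = q.E.row(x[t]).t();
  arma::mat dX(q.E.n_cols, n, arma::fill::zeros);
  lstm_backward(q.Wxf, q.Whf, X, false, cf, dH.rows(0, Hn - 1),
                gr.g.Wxf, gr.g.Whf, gr.g.bf, dX);
  lstm_backward(q.Wxb, q.Whb, X, true, cb, dH.rows(Hn, 2 * Hn - 1),
                gr.g.Wxb, gr.g.Whb, gr.g.bb, dX);
  for (arma::uword t = 0; t < n; ++t) gr.g.E.row(x[t]) += dX.col(t).t();
  return nll;
}

static void adam_update(arma::mat& w, arma::mat& m, arma::mat& v,
                        const arma::mat& g, double lr, double t,
                        double b1 = 0.9, double b2 = 0.999,
                        double eps = 1e-8) {
  m = b1 * m + (1.0 - b1) * g;
  v = b2 * v + (1.0 - b2) * (g % g);
  arma::mat mh = m / (1.0 - std::pow(b1, t));
  arma::mat vh = v / (1.0 - std::pow(b2, t));
  w -= lr * mh / (arma::sqrt(vh) + eps);
}

static void adam_update_vec(arma::vec& w, arma::vec& m, arma::vec& v,
                            const arma::vec& g, double lr, double t) {
  m = 0.9 * m + 0.1 * g;
  v = 0.999 * v + 0.001 * (g % g);
  arma::vec mh = m / (1.0 - std::pow(0.9, t));
  arma::vec vh = v / (1.0 - std::pow(0.999, t));
  w -= lr * mh / (arma::sqrt(vh) + 1e-8);
}

static double grad_global_norm(const Grads& gr) {
  double s = 0.0;
  s += arma::accu(arma::square(gr.g.E));
  s += arma::accu(arma::square(gr.g.Wxf)) + arma::accu(arma::square(gr.g.Whf));
  s += arma::accu(arma::square(gr.g.bf));
  s += arma::accu(arma::square(gr.g.Wxb)) + arma::accu(arma::square(gr.g.Whb));
  s += arma::accu(arma::square(gr.g.bb));
  s += arma::accu(arma::square(gr.g.Wo)) + arma::accu(arma::square(gr.g.bo));
  s += arma::accu(arma::square(gr.g.A));
  return std::sqrt(s);
}

static void scale_grads(Grads& gr, double f) {
  gr.g.E *= f; gr.g.Wxf *= f; gr.g.Whf *= f; gr.g.bf *= f;
  gr.g.Wxb *= f; gr.g.Whb *= f; gr.g.bb *= f;
  gr.g.Wo *= f; gr.g.bo *= f; gr.g.A *= f;
}

// [[Rcpp::export]]
List cpp_train_epoch(List params, List adam_m, List adam_v, int adam_t,
                     List xs, List ys, IntegerVector order, double lr,
                     double dropout, int batch_size, int seed,
                     double grad_clip = 5.0) {
  TaggerParams q = params_from_list(params);
  TaggerParams m = params_from_list(adam_m);
  TaggerParams v = params_from_list(adam_v);
  std::mt19937 rng(static_cast<unsigned int>(seed));
  const double keep = 1.0 - dropout;
  const int nseq = order.size();
  double nll_sum = 0.0;
  int done = 0;
  while (done < nseq) {
    int bs = std::min(batch_size, nseq - done);
    Grads gr(q);
    for (int b = 0; b < bs; ++b) {
      int si = order[done + b] - 1;
      arma::uvec x = as<arma::uvec>(xs[si]) - 1;  // R is 1-based
      arma::uvec y = as<arma::uvec>(ys[si]) - 1;
      if (x.n_elem == 0) continue;
      nll_sum += sequence_grad(q, x, y, keep, rng, gr);
    }
    done += bs;
    scale_grads(gr, 1.0 / bs);
    double gn = grad_global_norm(gr);
    if (grad_clip > 0 && gn > grad_clip) scale_grads(gr, grad_clip / gn);
    adam_t += 1;
    double t = static_cast<double>(adam_t);
    adam_update(q.E, m.E, v.E, gr.g.E, lr, t);
    adam_update(q.Wxf, m.Wxf, v.Wxf, gr.g.Wxf, lr, t);
    adam_update(q.Whf, m.Whf, v.Whf, gr.g.Whf, lr, t);
    adam_update_vec(q.bf, m.bf, v.bf, gr.g.bf, lr, t);
    adam_update(q.Wxb, m.Wxb, v.Wxb, gr.g.Wxb, lr, t);
    adam_update(q.Whb, m.Whb, v.Whb, gr.g.Whb, lr, t);
    adam_update_vec(q.bb, m.bb, v.bb, gr.g.bb, lr, t);
    adam_update(q.Wo, m.Wo, v.Wo, gr.g.Wo, lr, t);
    adam_update_vec(q.bo, m.bo, v.bo, gr.g.bo, lr, t);
    adam_update(q.A, m.A, v.A, gr.g.A, lr, t);
  }
  return List::create(
    Named("params") = params_to_list(q), Named("m") = params_to_list(m),
    Named("v") = params_to_list(v), Named("t") = adam_t,
    Named("nll") = nll_sum / std::max(nseq, 1));
}

// [[Rcpp::export]]
List cpp_predict_tags(List params, List xs) {
  TaggerParams q = params_from_list(params);
  const int nseq = xs.size();
  List out(nseq);
  for (int s = 0; s < nseq; ++s) {
    arma::uvec x = as<arma::uvec>(xs[s]) - 1;
    if (x.n_elem == 0) { out[s] = IntegerVector(0); continue; }
    LstmCache cf, cb;
    arma::mat Hcat;
    arma::mat P = emissions_for(q, x, cf, cb, Hcat);
    arma::uvec path = viterbi_path(P, q.A) + 1;  // back to 1-based
    out[s] = IntegerVector(path.begin(), path.end());
  }
  return out;
}

// [[Rcpp::export]]
arma::mat cpp_emissions(List params, IntegerVector x) {
  TaggerParams q = params_from_list(params);
  arma::uvec xu = as<arma::uvec>(x) - 1;
  if (xu.n_elem == 0) return arma::mat(0, q.Wo.n_rows);
  LstmCache cf, cb;
  arma::mat Hcat;
  arma::mat P = emissions_for(q, xu, cf, cb, Hcat);
  return P.t();  // n x k, the R-side emission convention
}

// Exact analytic gradients of one sequence's NLL (no dropout); exposed so
// the backward pass can be verified against finite differences.
// [[Rcpp::export]]
List cpp_sequence_grads(List params, IntegerVector x, IntegerVector y) {
  TaggerParams q = params_from_list(params);
  arma::uvec xu = as<arma::uvec>(x) - 1, yu = as<arma::uvec>(y) - 1;
  Grads gr(q);
  std::mt19937 rng(1u);
  double nll = sequence_grad(q, xu, yu, 1.0, rng, gr);
  List out = params_to_list(gr.g);
  out["nll"] = nll;
  return out;
}

// [[Rcpp::export]]
double cpp_sequence_nll(List params, IntegerVector x, IntegerVector y) {
  TaggerParams q = params_from_list(params);
  arma::uvec xu = as<arma::uvec>(x) - 1, yu = as<arma::uvec>(y) - 1;
  LstmCache cf, cb;
  arma::mat Hcat;
  arma::mat P = emissions_for(q, xu, cf, cb, Hcat);
  arma::mat dP, dA(arma::size(q.A), arma::fill::zeros);
  return crf_nll_grad(P, q.A, yu, dP, dA);
}
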