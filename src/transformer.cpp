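// Miniature decoder-only transformer with causal sliding-window (local)
// attention, trained on the next-code objective by Adam with manual
// backpropagation. Pre-LayerNorm residual blocks, GELU feed-forward,
// learned positional embeddings, untied output projection. Sized for
// desk-scale corpora (hidden 32-64, 1-2 layers); all computation is exact
// dense linear algebra via Armadillo and fully deterministic given a seed.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;

struct Cfg {
  int V, L, d, layers, heads, window;
  double lr, beta1, beta2, eps, clip;
  int batch_tokens, max_steps, eval_every, patience;
  unsigned int seed;
};

static Cfg read_cfg(const List& cfg) {
  Cfg c;
  c.V = cfg["vocab_size"]; c.L = cfg["max_seq_len"]; c.d = cfg["hidden_size"];
  c.layers = cfg["n_layers"]; c.heads = cfg["n_heads"];
  c.window = cfg["attn_window"];
  c.lr = cfg.containsElementNamed("lr") ? as<double>(cfg["lr"]) : 1e-3;
  c.beta1 = 0.9; c.beta2 = 0.999; c.eps = 1e-8;
  c.clip = cfg.containsElementNamed("grad_clip") ? as<double>(cfg["grad_clip"]) : 1.0;
  c.batch_tokens = cfg.containsElementNamed("batch_tokens") ? as<int>(cfg["batch_tokens"]) : 512;
  c.max_steps = cfg.containsElementNamed("max_steps") ? as<int>(cfg["max_steps"]) : 1000;
  c.eval_every = cfg.containsElementNamed("eval_every") ? as<int>(cfg["eval_every"]) : 25;
  c.patience = cfg.containsElementNamed("patience") ? as<int>(cfg["patience"]) : 500;
  c.seed = cfg.containsElementNamed("seed") ? as<unsigned int>(cfg["seed"]) : 1u;
  if (c.d % c.heads != 0) stop("hidden_size must be divisible by n_heads");
  return c;
}

static std::vector<std::string> param_names(const Cfg& c) {
  std::vector<std::string> nm = {"emb", "pos"};
  for (int l = 0; l < c.layers; ++l) {
    std::string p = "l" + std::to_string(l) + "_";
    for (const char* s : {"ln1_g", "ln1_b", "wq", "wk", "wv", "wo", "bo",
                          "ln2_g", "ln2_b", "w1", "b1", "w2", "b2"})
      nm.push_back(p + s);
  }
  nm.push_back("lnf_g"); nm.push_back("lnf_b");
  nm.push_back("wout"); nm.push_back("bout");
  return nm;
}

static std::vector<mat> list_to_params(const List& pl, const Cfg& c) {
  std::vector<std::string> nm = param_names(c);
  std::vector<mat> P;
  P.reserve(nm.size());
  for (auto& n : nm) {
    if (!pl.containsElementNamed(n.c_str())) stop("missing parameter: " + n);
    P.push_back(as<mat>(pl[n]));
  }
  return P;
}

static List params_to_list(const std::vector<mat>& P, const Cfg& c) {
  std::vector<std::string> nm = param_names(c);
  List out(nm.size());
  CharacterVector names(nm.size());
  for (size_t i = 0; i < nm.size(); ++i) { out[i] = P[i]; names[i] = nm[i]; }
  out.attr("names") = names;
  return out;
}

// [[Rcpp::export(name = ".cpp_fm_init")]]
List cpp_fm_init(List cfg) {
  Cfg c = read_cfg(cfg);
  std::mt19937 rng(c.seed);
  std::normal_distribution<double> nd(0.0, 0.02);
  auto rnd = [&](int r, int cc) {
    mat m(r, cc);
    for (arma::uword j = 0; j < m.n_cols; ++j)
      for (arma::uword i = 0; i < m.n_rows; ++i) m(i, j) = nd(rng);
    return m;
  };
  std::vector<mat> P;
  P.push_back(rnd(c.V, c.d));                 // emb
  P.push_back(rnd(c.L, c.d));                 // pos
  for (int l = 0; l < c.layers; ++l) {
    P.push_back(mat(1, c.d, arma::fill::ones));   // ln1_g
    P.push_back(mat(1, c.d, arma::fill::zeros));  // ln1_b
    P.push_back(rnd(c.d, c.d));                   // wq
    P.push_back(rnd(c.d, c.d));                   // wk
    P.push_back(rnd(c.d, c.d));                   // wv
    P.push_back(rnd(c.d, c.d));                   // wo
    P.push_back(mat(1, c.d, arma::fill::zeros));  // bo
    P.push_back(mat(1, c.d, arma::fill::ones));   // ln2_g
    P.push_back(mat(1, c.d, arma::fill::zeros));  // ln2_b
    P.push_back(rnd(c.d, 4 * c.d));               // w1
    P.push_back(mat(1, 4 * c.d, arma::fill::zeros)); // b1
    P.push_back(rnd(4 * c.d, c.d));               // w2
    P.push_back(mat(1, c.d, arma::fill::zeros));  // b2
  }
  P.push_back(mat(1, c.d, arma::fill::ones));     // lnf_g
  P.push_back(mat(1, c.d, arma::fill::zeros));    // lnf_b
  P.push_back(rnd(c.d, c.V));                     // wout
  P.push_back(mat(1, c.V, arma::fill::zeros));    // bout
  return params_to_list(P, c);
}

static const double LN_EPS = 1e-5;

// layer norm over rows; caches xhat and inv std
static mat layer_norm(const mat& x, const mat& g, const mat& b,
                      mat& xhat, arma::vec& istd) {
  const arma::uword n = x.n_rows, d = x.n_cols;
  xhat.set_size(n, d); istd.set_size(n);
  mat out(n, d);
  for (arma::uword i = 0; i < n; ++i) {
    double mu = arma::mean(x.row(i));
    double va = arma::accu(arma::square(x.row(i) - mu)) / d;
    double is = 1.0 / std::sqrt(va + LN_EPS);
    istd(i) = is;
    xhat.row(i) = (x.row(i) - mu) * is;
    out.row(i) = xhat.row(i) % g + b;
  }
  return out;
}

static mat layer_norm_bwd(const mat& dy, const mat& xhat, const arma::vec& istd,
                          const mat& g, mat& dg, mat& db) {
  const arma::uword n = dy.n_rows, d = dy.n_cols;
  dg += arma::sum(dy % xhat, 0);
  db += arma::sum(dy, 0);
  mat dx(n, d);
  for (arma::uword i = 0; i < n; ++i) {
    rowvec dyg = dy.row(i) % g;
    double m1 = arma::mean(dyg);
    double m2 = arma::mean(dyg % xhat.row(i));
    dx.row(i) = (dyg - m1 - xhat.row(i) * m2) * istd(i);
  }
  return dx;
}

static mat gelu(const mat& x) {
  return x % arma::normcdf(x);
}
static mat gelu_grad(const mat& x) {
  return arma::normcdf(x) + x % arma::normpdf(x);
}

// per-sequence caches for backprop
struct LayerCache {
  mat x_in, xhat1, xn1, Q, K, Vv, C, x_mid, xhat2, xn2, A, H;
  arma::vec istd1, istd2;
  std::vector<mat> Pmat;  // per-head attention weights
};
struct SeqCache {
  mat x0;
  std::vector<LayerCache> layers;
  mat xhatf, xf;
  arma::vec istdf;
};

// forward pass; returns final-layer hidden states (after final LN)
static mat fm_forward(const std::vector<mat>& P, const arma::ivec& tok,
                      const Cfg& c, SeqCache& cache) {
  const int n = tok.n_elem;
  const int dh = c.d / c.heads;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dh));
  mat x(n, c.d);
  for (int t = 0; t < n; ++t)
    x.row(t) = P[0].row(tok(t)) + P[1].row(t);
  cache.x0 = x;
  cache.layers.resize(c.layers);
  int pi = 2;
  for (int l = 0; l < c.layers; ++l) {
    LayerCache& L = cache.layers[l];
    const mat& g1 = P[pi], &b1 = P[pi + 1], &wq = P[pi + 2], &wk = P[pi + 3],
      &wv = P[pi + 4], &wo = P[pi + 5], &bo = P[pi + 6], &g2 = P[pi + 7],
      &b2 = P[pi + 8], &W1 = P[pi + 9], &bb1 = P[pi + 10], &W2 = P[pi + 11],
      &bb2 = P[pi + 12];
    L.x_in = x;
    L.xn1 = layer_norm(x, g1, b1, L.xhat1, L.istd1);
    L.Q = L.xn1 * wq; L.K = L.xn1 * wk; L.Vv = L.xn1 * wv;
    L.C.set_size(n, c.d);
    L.Pmat.resize(c.heads);
    for (int h = 0; h < c.heads; ++h) {
      mat Qh = L.Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = L.K.cols(h * dh, (h + 1) * dh - 1);
      mat Vh = L.Vv.cols(h * dh, (h + 1) * dh - 1);
      mat S = Qh * Kh.t() * scale;
      for (int i = 0; i < n; ++i) {
        int lo = std::max(0, i - c.window + 1);
        for (int j = 0; j < n; ++j)
          if (j > i || j < lo) S(i, j) = -1e30;
      }
      mat Pm(n, n);
      for (int i = 0; i < n; ++i) {
        rowvec r = S.row(i);
        double mx = r.max();
        r = arma::exp(r - mx);
        Pm.row(i) = r / arma::accu(r);
      }
      L.Pmat[h] = Pm;
      L.C.cols(h * dh, (h + 1) * dh - 1) = Pm * Vh;
    }
    mat attn = L.C * wo;
    attn.each_row() += bo;
    x = x + attn;
    L.x_mid = x;
    L.xn2 = layer_norm(x, g2, b2, L.xhat2, L.istd2);
    L.A = L.xn2 * W1;
    L.A.each_row() += bb1;
    L.H = gelu(L.A);
    mat m = L.H * W2;
    m.each_row() += bb2;
    x = x + m;
    pi += 13;
  }
  cache.xf = layer_norm(x, P[pi], P[pi + 1], cache.xhatf, cache.istdf);
  return cache.xf;
}

// cross-entropy of next-token prediction; accumulates parameter gradients
// scaled by `gscale` into G when G is non-null. Returns summed loss over
// the n-1 predicted positions (n_pred out-param).
static double fm_loss_grad(const std::vector<mat>& P, const arma::ivec& tok,
                           const Cfg& c, std::vector<mat>* G, double gscale,
                           int& n_pred) {
  const int n = tok.n_elem;
  n_pred = n - 1;
  if (n < 2) { n_pred = 0; return 0.0; }
  SeqCache cache;
  mat xf = fm_forward(P, tok, c, cache);
  const int pi_f = 2 + 13 * c.layers;
  const mat& wout = P[pi_f + 2], &bout = P[pi_f + 3];
  // logits only needed at positions 0..n-2
  mat xf_p = xf.rows(0, n - 2);
  mat logits = xf_p * wout;
  logits.each_row() += bout;
  double loss = 0.0;
  mat dlogits(n - 1, c.V);
  for (int t = 0; t < n - 1; ++t) {
    rowvec r = logits.row(t);
    double mx = r.max();
    rowvec e = arma::exp(r - mx);
    double Z = arma::accu(e);
    rowvec p = e / Z;
    loss += -(std::log(p(tok(t + 1)) + 1e-300));
    if (G) {
      dlogits.row(t) = p;
      dlogits(t, tok(t + 1)) -= 1.0;
    }
  }
  if (!G) return loss;

  std::vector<mat>& Gr = *G;
  dlogits *= gscale;
  Gr[pi_f + 2] += xf_p.t() * dlogits;
  Gr[pi_f + 3] += arma::sum(dlogits, 0);
  mat dxf(n, c.d, arma::fill::zeros);
  dxf.rows(0, n - 2) = dlogits * wout.t();
  mat dx = layer_norm_bwd(dxf, cache.xhatf, cache.istdf, P[pi_f],
                          Gr[pi_f], Gr[pi_f + 1]);
  const int dh = c.d / c.heads;
  const double scale = 1.0 / std::sqrt(static_cast<double>(dh));
  for (int l = c.layers - 1; l >= 0; --l) {
    int pi = 2 + 13 * l;
    LayerCache& L = cache.layers[l];
    const mat& wq = P[pi + 2], &wk = P[pi + 3], &wv = P[pi + 4],
      &wo = P[pi + 5], &W1 = P[pi + 9], &W2 = P[pi + 11];
    // MLP block
    mat dm = dx;                       // gradient into the mlp output branch
    mat dH = dm * W2.t();
    Gr[pi + 11] += L.H.t() * dm;
    Gr[pi + 12] += arma::sum(dm, 0);
    mat dA = dH % gelu_grad(L.A);
    Gr[pi + 9] += L.xn2.t() * dA;
    Gr[pi + 10] += arma::sum(dA, 0);
    mat dxn2 = dA * W1.t();
    mat dx_mid = layer_norm_bwd(dxn2, L.xhat2, L.istd2, P[pi + 7],
                                Gr[pi + 7], Gr[pi + 8]);
    dx_mid += dx;                      // residual
    // attention block
    mat dattn = dx_mid;
    Gr[pi + 5] += L.C.t() * dattn;
    Gr[pi + 6] += arma::sum(dattn, 0);
    mat dC = dattn * wo.t();
    mat dQ(arma::size(L.Q), arma::fill::zeros);
    mat dK(arma::size(L.K), arma::fill::zeros);
    mat dV(arma::size(L.Vv), arma::fill::zeros);
    for (int h = 0; h < c.heads; ++h) {
      mat dCh = dC.cols(h * dh, (h + 1) * dh - 1);
      const mat& Pm = L.Pmat[h];
      mat Vh = L.Vv.cols(h * dh, (h + 1) * dh - 1);
      mat dP = dCh * Vh.t();
      dV.cols(h * dh, (h + 1) * dh - 1) = Pm.t() * dCh;
      mat dS(arma::size(Pm));
      for (arma::uword i = 0; i < Pm.n_rows; ++i) {
        rowvec pi_r = Pm.row(i);
        rowvec dp = dP.row(i);
        double dot = arma::accu(dp % pi_r);
        dS.row(i) = pi_r % (dp - dot);
      }
      mat Qh = L.Q.cols(h * dh, (h + 1) * dh - 1);
      mat Kh = L.K.cols(h * dh, (h + 1) * dh - 1);
      dQ.cols(h * dh, (h + 1) * dh - 1) = dS * Kh * scale;
      dK.cols(h * dh, (h + 1) * dh - 1) = dS.t() * Qh * scale;
    }
    Gr[pi + 2] += L.xn1.t() * dQ;
    Gr[pi + 3] += L.xn1.t() * dK;
    Gr[pi + 4] += L.xn1.t() * dV;
    mat dxn1 = dQ * wq.t() + dK * wk.t() + dV * wv.t();
    mat dx_in = layer_norm_bwd(dxn1, L.xhat1, L.istd1, P[pi],
                               Gr[pi], Gr[pi + 1]);
    dx = dx_mid + dx_in;
  }
  for (int t = 0; t < n; ++t) {
    Gr[0].row(tok(t)) += dx.row(t);
    Gr[1].row(t) += dx.row(t);
  }
  return loss;
}

static std::vector<arma::ivec> seq_list(const List& seqs, const Cfg& c) {
  std::vector<arma::ivec> out;
  out.reserve(seqs.size());
  for (int i = 0; i < seqs.size(); ++i) {
    IntegerVector s = seqs[i];
    if (s.size() > c.L) stop("sequence longer than max_seq_len");
    arma::ivec v(s.size());
    for (int j = 0; j < s.size(); ++j) {
      if (s[j] < 0 || s[j] >= c.V) stop("token index out of range");
      v(j) = s[j];
    }
    out.push_back(v);
  }
  return out;
}

static double eval_loss(const std::vector<mat>& P,
                        const std::vector<arma::ivec>& seqs, const Cfg& c) {
  double loss = 0.0; long ntok = 0;
  int np;
  for (const auto& s : seqs) {
    if (s.n_elem < 2) continue;
    loss += fm_loss_grad(P, s, c, nullptr, 0.0, np);
    ntok += np;
  }
  if (ntok == 0) stop("no evaluable sequences (all shorter than 2 tokens)");
  return loss / ntok;
}

// [[Rcpp::export(name = ".cpp_fm_loss")]]
double cpp_fm_loss(List params, List seqs, List cfg) {
  Cfg c = read_cfg(cfg);
  std::vector<mat> P = list_to_params(params, c);
  return eval_loss(P, seq_list(seqs, c), c);
}

// [[Rcpp::export(name = ".cpp_fm_grad")]]
List cpp_fm_grad(List params, List seqs, List cfg) {
  Cfg c = read_cfg(cfg);
  std::vector<mat> P = list_to_params(params, c);
  std::vector<arma::ivec> ss = seq_list(seqs, c);
  std::vector<mat> G;
  for (auto& p : P) G.push_back(mat(arma::size(p), arma::fill::zeros));
  long ntok = 0; int np;
  for (const auto& s : ss) if (s.n_elem >= 2) ntok += s.n_elem - 1;
  if (ntok == 0) stop("no evaluable sequences");
  double loss = 0.0;
  for (const auto& s : ss) {
    if (s.n_elem < 2) continue;
    loss += fm_loss_grad(P, s, c, &G, 1.0 / ntok, np);
  }
  return List::create(_["loss"] = loss / ntok,
                      _["grads"] = params_to_list(G, c));
}

// [[Rcpp::export(name = ".cpp_fm_hidden")]]
NumericMatrix cpp_fm_hidden(List params, IntegerVector seq, List cfg) {
  Cfg c = read_cfg(cfg);
  std::vector<mat> P = list_to_params(params, c);
  List one = List::create(seq);
  std::vector<arma::ivec> s = seq_list(one, c);
  SeqCache cache;
  mat xf = fm_forward(P, s[0], c, cache);
  return wrap(xf);
}

// [[Rcpp::export(name = ".cpp_fm_train")]]
List cpp_fm_train(List params, List train, List valid, List cfg) {
  Cfg c = read_cfg(cfg);
  std::vector<mat> P = list_to_params(params, c);
  std::vector<arma::ivec> tr = seq_list(train, c);
  std::vector<arma::ivec> va = seq_list(valid, c);
  // drop sequences with fewer than 2 tokens (no prediction target)
  tr.erase(std::remove_if(tr.begin(), tr.end(),
           [](const arma::ivec& s) { return s.n_elem < 2; }), tr.end());
  if (tr.empty()) stop("empty training corpus");
  std::mt19937 rng(c.seed + 17u);
  std::uniform_int_distribution<size_t> draw(0, tr.size() - 1);

  std::vector<mat> M, Vt, G, best;
  for (auto& p : P) {
    M.push_back(mat(arma::size(p), arma::fill::zeros));
    Vt.push_back(mat(arma::size(p), arma::fill::zeros));
    G.push_back(mat(arma::size(p), arma::fill::zeros));
  }
  double best_loss = eval_loss(P, va, c);
  best = P;
  int best_step = 0;
  std::vector<double> hist_steps, hist_losses;
  hist_steps.push_back(0); hist_losses.push_back(best_loss);

  int step = 0;
  while (step < c.max_steps) {
    ++step;
    // assemble a batch meeting the token budget
    std::vector<size_t> batch;
    int tok_budget = 0;
    while (tok_budget < c.batch_tokens) {
      size_t i = draw(rng);
      batch.push_back(i);
      tok_budget += tr[i].n_elem - 1;
    }
    for (auto& g : G) g.zeros();
    double gscale = 1.0 / tok_budget;
    double batch_loss = 0.0; int np;
    for (size_t i : batch) batch_loss += fm_loss_grad(P, tr[i], c, &G, gscale, np);
    batch_loss /= tok_budget;
    if (!std::isfinite(batch_loss))
      stop("training diverged: non-finite loss at step " + std::to_string(step));
    // global gradient-norm clipping
    double gn2 = 0.0;
    for (auto& g : G) gn2 += arma::accu(arma::square(g));
    double gn = std::sqrt(gn2);
    double cl = (c.clip > 0 && gn > c.clip) ? c.clip / gn : 1.0;
    double bc1 = 1.0 - std::pow(c.beta1, step);
    double bc2 = 1.0 - std::pow(c.beta2, step);
    for (size_t k = 0; k < P.size(); ++k) {
      mat g = G[k] * cl;
      M[k] = c.beta1 * M[k] + (1 - c.beta1) * g;
      Vt[k] = c.beta2 * Vt[k] + (1 - c.beta2) * arma::square(g);
      P[k] -= c.lr * (M[k] / bc1) / (arma::sqrt(Vt[k] / bc2) + c.eps);
    }
    if (step % c.eval_every == 0 || step == c.max_steps) {
      double vl = eval_loss(P, va, c);
      hist_steps.push_back(step); hist_losses.push_back(vl);
      if (vl < best_loss - 1e-6) {
        best_loss = vl; best = P; best_step = step;
      } else if (step - best_step >= c.patience) {
        break;
      }
    }
  }
  return List::create(
    _["params"] = params_to_list(best, c),
    _["steps"] = step,
    _["best_step"] = best_step,
    _["valid_loss"] = best_loss,
    _["history"] = DataFrame::create(_["step"] = hist_steps,
                                     _["valid_loss"] = hist_losses));
}
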