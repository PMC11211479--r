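// Fast metric kernels shared by the R-level evaluation API and the
// hierarchical bootstrap loop. AUROC uses midrank tie handling; ECE uses
// type-7 quantile bin edges with duplicate edges merged.
#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static double auroc_kernel(const arma::vec& score, const arma::ivec& label) {
  const arma::uword n = score.n_elem;
  arma::uvec ord = arma::sort_index(score);
  arma::vec rank(n);
  arma::uword i = 0;
  while (i < n) {
    arma::uword j = i;
    while (j + 1 < n && score(ord(j + 1)) == score(ord(i))) ++j;
    double avg = 0.5 * (static_cast<double>(i + 1) + static_cast<double>(j + 1));
    for (arma::uword k = i; k <= j; ++k) rank(ord(k)) = avg;
    i = j + 1;
  }
  double n1 = 0, rsum = 0;
  for (arma::uword k = 0; k < n; ++k) {
    if (label(k) == 1) { n1 += 1.0; rsum += rank(k); }
  }
  double n0 = static_cast<double>(n) - n1;
  if (n1 == 0 || n0 == 0) return NA_REAL;
  return (rsum - n1 * (n1 + 1.0) / 2.0) / (n1 * n0);
}

static double quantile7(const arma::vec& sorted, double p) {
  const arma::uword n = sorted.n_elem;
  if (n == 1) return sorted(0);
  double h = (static_cast<double>(n) - 1.0) * p;
  arma::uword lo = static_cast<arma::uword>(std::floor(h));
  if (lo >= n - 1) return sorted(n - 1);
  return sorted(lo) + (h - lo) * (sorted(lo + 1) - sorted(lo));
}

static double ece_kernel(const arma::vec& p, const arma::ivec& y, int bins) {
  const arma::uword n = p.n_elem;
  arma::vec sorted = arma::sort(p);
  std::vector<double> edges;
  for (int b = 0; b <= bins; ++b) {
    double e = quantile7(sorted, static_cast<double>(b) / bins);
    if (edges.empty() || e > edges.back()) edges.push_back(e);
  }
  double ybar = 0;
  for (arma::uword k = 0; k < n; ++k) ybar += y(k);
  ybar /= n;
  if (edges.size() < 3) {  // all risks in one bin
    return std::abs(arma::mean(p) - ybar);
  }
  const int nb = static_cast<int>(edges.size()) - 1;
  std::vector<double> cnt(nb, 0.0), psum(nb, 0.0), ysum(nb, 0.0);
  for (arma::uword k = 0; k < n; ++k) {
    // first bin closed on the left, others (lo, hi]
    int b = nb - 1;
    for (int j = 0; j < nb; ++j) {
      if (p(k) <= edges[j + 1]) { b = j; break; }
    }
    cnt[b] += 1.0; psum[b] += p(k); ysum[b] += y(k);
  }
  double ece = 0;
  for (int j = 0; j < nb; ++j) {
    if (cnt[j] > 0) ece += (cnt[j] / n) * std::abs(psum[j] / cnt[j] - ysum[j] / cnt[j]);
  }
  return ece;
}

// [[Rcpp::export(name = ".cpp_auroc")]]
double cpp_auroc(NumericVector score, IntegerVector label) {
  arma::vec s(score.begin(), score.size(), false);
  arma::ivec y(label.begin(), label.size(), false);
  return auroc_kernel(s, y);
}

// [[Rcpp::export(name = ".cpp_ece")]]
double cpp_ece(NumericVector p, IntegerVector label, int bins) {
  arma::vec pv(p.begin(), p.size(), false);
  arma::ivec y(label.begin(), label.size(), false);
  return ece_kernel(pv, y, bins);
}

// Hierarchical bootstrap of the mean metric difference between two models
// evaluated on identical example sets. `tasks` is a list; each element is a
// list(a = numeric, b = numeric, y = integer). Replicates resample tasks
// with replacement (when nested), then examples with replacement within each
// resampled task.
// [[Rcpp::export(name = ".cpp_hier_bootstrap")]]
NumericVector cpp_hier_bootstrap(List tasks, int B, int seed, bool nested,
                                 std::string metric, int bins) {
  const int T = tasks.size();
  std::vector<arma::vec> A(T), Bv(T);
  std::vector<arma::ivec> Y(T);
  for (int t = 0; t < T; ++t) {
    List tl = tasks[t];
    NumericVector a = tl["a"], b = tl["b"];
    IntegerVector y = tl["y"];
    A[t] = arma::vec(a.begin(), a.size());
    Bv[t] = arma::vec(b.begin(), b.size());
    Y[t] = arma::ivec(y.begin(), y.size());
  }
  const bool use_auroc = (metric == "auroc");
  std::mt19937 rng(static_cast<unsigned int>(seed));
  std::uniform_int_distribution<int> task_draw(0, T - 1);
  NumericVector out(B);
  for (int r = 0; r < B; ++r) {
    double acc = 0; int used = 0;
    for (int ti = 0; ti < T; ++ti) {
      int t = nested ? task_draw(rng) : ti;
      const arma::uword n = Y[t].n_elem;
      std::uniform_int_distribution<arma::uword> ex_draw(0, n - 1);
      double ma = NA_REAL, mb = NA_REAL;
      for (int attempt = 0; attempt < 1000; ++attempt) {
        arma::uvec idx(n);
        for (arma::uword k = 0; k < n; ++k) idx(k) = ex_draw(rng);
        arma::ivec yy = Y[t](idx);
        if (use_auroc) {
          // AUROC needs both classes in the resample
          if (arma::accu(yy) == 0 || arma::accu(yy) == static_cast<int>(n)) continue;
          ma = auroc_kernel(A[t](idx), yy);
          mb = auroc_kernel(Bv[t](idx), yy);
        } else {
          ma = ece_kernel(A[t](idx), yy, bins);
          mb = ece_kernel(Bv[t](idx), yy, bins);
        }
        break;
      }
      if (R_finite(ma) && R_finite(mb)) { acc += ma - mb; ++used; }
    }
    out[r] = used > 0 ? acc / used : NA_REAL;
  }
  return out;
}
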