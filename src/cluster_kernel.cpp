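// Cluster-based sign-flip permutation kernel for paired time-frequency
// contrasts. Cells are a (nf x nt) lattice stored column-major with
// frequency fastest; adjacency is 4-neighbour (no diagonals). The cluster
// statistic is the sum of per-cell paired t values over a maximal connected
// component of same-sign supra-threshold cells; per permutation we keep the
// maximum |t-sum| pooled over both signs.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double cell_t(double sum, double sumsq, int n) {
  double mean = sum / n;
  double var = (sumsq - n * mean * mean) / (n - 1);
  if (var <= 0.0) {
    if (mean == 0.0) return 0.0;
    return mean > 0 ? 1e12 : -1e12;
  }
  return mean / std::sqrt(var / n);
}

// flood fill over same-sign supra-threshold cells, returning max |t-sum|
static double max_abs_tsum(const std::vector<double>& t, int nf, int nt,
                           double tcrit, std::vector<int>& labels,
                           std::vector<double>& sums, bool keep_labels) {
  int m = nf * nt;
  std::vector<int> lab(m, 0);
  std::vector<int> stack;
  double best = 0.0;
  int next_label = 0;
  for (int s = 0; s < m; ++s) {
    if (lab[s] != 0 || std::fabs(t[s]) < tcrit) continue;
    ++next_label;
    int sgn = t[s] > 0 ? 1 : -1;
    double sum = 0.0;
    stack.clear();
    stack.push_back(s);
    lab[s] = next_label;
    while (!stack.empty()) {
      int c = stack.back();
      stack.pop_back();
      sum += t[c];
      int f = c % nf, ti = c / nf;
      int nb[4] = {f > 0 ? c - 1 : -1, f < nf - 1 ? c + 1 : -1,
                   ti > 0 ? c - nf : -1, ti < nt - 1 ? c + nf : -1};
      for (int k = 0; k < 4; ++k) {
        int q = nb[k];
        if (q < 0 || lab[q] != 0) continue;
        if (std::fabs(t[q]) < tcrit) continue;
        if ((t[q] > 0 ? 1 : -1) != sgn) continue;
        lab[q] = next_label;
        stack.push_back(q);
      }
    }
    if (keep_labels) sums.push_back(sum);
    if (std::fabs(sum) > best) best = std::fabs(sum);
  }
  if (keep_labels) labels = lab;
  return best;
}

// [[Rcpp::export(name = ".cluster_label")]]
List cluster_label(NumericVector tmap, int nf, int nt, double tcrit) {
  std::vector<double> t(tmap.begin(), tmap.end());
  std::vector<int> labels;
  std::vector<double> sums;
  max_abs_tsum(t, nf, nt, tcrit, labels, sums, true);
  return List::create(_["labels"] = IntegerVector(labels.begin(), labels.end()),
                      _["tsums"] = NumericVector(sums.begin(), sums.end()));
}

// X: n x m matrix of participant difference maps (m = nf*nt, column-major
// cells); signs: nperm x n matrix of +/-1. Returns max |t-sum| per perm.
// [[Rcpp::export(name = ".perm_max_tsums")]]
NumericVector perm_max_tsums(NumericMatrix X, int nf, int nt,
                             IntegerMatrix signs, double tcrit) {
  int n = X.nrow(), m = X.ncol(), nperm = signs.nrow();
  if (signs.ncol() != n) stop("signs must have one column per participant");
  if (m != nf * nt) stop("map size mismatch");
  std::vector<double> sumsq(m, 0.0);
  for (int j = 0; j < m; ++j) {
    double s = 0.0;
    for (int i = 0; i < n; ++i) s += X(i, j) * X(i, j);
    sumsq[j] = s;
  }
  NumericVector out(nperm);
  std::vector<double> t(m);
  std::vector<int> dummy_lab;
  std::vector<double> dummy_sums;
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < m; ++j) {
      double s = 0.0;
      for (int i = 0; i < n; ++i) s += signs(p, i) * X(i, j);
      t[j] = cell_t(s, sumsq[j], n);
    }
    out[p] = max_abs_tsum(t, nf, nt, tcrit, dummy_lab, dummy_sums, false);
  }
  return out;
}
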