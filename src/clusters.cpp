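#include <Rcpp.h>
using namespace Rcpp;

// Connected components of same-sign supra-threshold bins on an
// nrow x ncol grid (4-connectivity; ncol == 1 gives 1-D adjacency).
// Values are t statistics laid out column-major.

static double maxMassOne(const double* t, int nrow, int ncol, double thresh,
                         std::vector<int>& stack, std::vector<char>& seen) {
  int n = nrow * ncol;
  std::fill(seen.begin(), seen.end(), 0);
  double best = 0.0;
  for (int s = 0; s < n; ++s) {
    if (seen[s] || !(t[s] > thresh || t[s] < -thresh)) continue;
    int sign = t[s] > 0 ? 1 : -1;
    double mass = 0.0;
    stack.clear();
    stack.push_back(s);
    seen[s] = 1;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      mass += t[c];
      int r = c % nrow, col = c / nrow;
      int nb[4] = {r > 0 ? c - 1 : -1, r < nrow - 1 ? c + 1 : -1,
                   col > 0 ? c - nrow : -1, col < ncol - 1 ? c + nrow : -1};
      for (int k = 0; k < 4; ++k) {
        int m = nb[k];
        if (m < 0 || seen[m]) continue;
        if ((sign > 0 && t[m] > thresh) || (sign < 0 && t[m] < -thresh)) {
          seen[m] = 1;
          stack.push_back(m);
        }
      }
    }
    if (std::abs(mass) > best) best = std::abs(mass);
  }
  return best;
}

// [[Rcpp::export]]
IntegerVector cpp_cluster_label(NumericVector t, int nrow, int ncol,
                                double thresh) {
  int n = nrow * ncol;
  IntegerVector lab(n, 0);
  std::vector<int> stack;
  int next = 0;
  for (int s = 0; s < n; ++s) {
    if (lab[s] != 0 || !(t[s] > thresh || t[s] < -thresh)) continue;
    int sign = t[s] > 0 ? 1 : -1;
    ++next;
    stack.clear();
    stack.push_back(s);
    lab[s] = next;
    while (!stack.empty()) {
      int c = stack.back(); stack.pop_back();
      int r = c % nrow, col = c / nrow;
      int nb[4] = {r > 0 ? c - 1 : -1, r < nrow - 1 ? c + 1 : -1,
                   col > 0 ? c - nrow : -1, col < ncol - 1 ? c + nrow : -1};
      for (int k = 0; k < 4; ++k) {
        int m = nb[k];
        if (m < 0 || lab[m] != 0) continue;
        if ((sign > 0 && t[m] > thresh) || (sign < 0 && t[m] < -thresh)) {
          lab[m] = next;
          stack.push_back(m);
        }
      }
    }
  }
  return lab;
}

// tmat: n_perm x n_bins matrix of permutation t maps; returns per
// permutation the maximum absolute cluster mass.
// [[Rcpp::export]]
NumericVector cpp_max_cluster_mass(NumericMatrix tmat, int nrow, int ncol,
                                   double thresh) {
  int nperm = tmat.nrow(), n = nrow * ncol;
  NumericVector out(nperm);
  std::vector<int> stack;
  std::vector<char> seen(n);
  std::vector<double> buf(n);
  for (int p = 0; p < nperm; ++p) {
    for (int j = 0; j < n; ++j) buf[j] = tmat(p, j);
    out[p] = maxMassOne(buf.data(), nrow, ncol, thresh, stack, seen);
  }
  return out;
}
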