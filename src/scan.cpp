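// Composite-likelihood scan cores. The sweep scan discretizes the compound
// parameter u = alpha * distance onto a log-spaced grid of precomputed
// sweep-perturbed spectra; sites with u > cutoff contribute exactly their
// background likelihood and cancel from the ratio.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// [[Rcpp::export]]
List sweep_scan_cpp(NumericVector pos, IntegerVector xcls, NumericVector logG,
                    NumericVector test_pos, NumericVector alpha,
                    double log_u0, double dlog, NumericMatrix logP,
                    double cutoff) {
  int S = pos.size(), Tn = test_pos.size(), A = alpha.size();
  int nb = logP.nrow();
  int K = logP.ncol();
  NumericVector clr(Tn), ahat(Tn);
  // net per-site contribution logP - logG, flattened bin-major
  std::vector<double> net((size_t)nb * K);
  for (int b = 0; b < nb; ++b)
    for (int k = 0; k < K; ++k) net[(size_t)b * K + k] = logP(b, k) - logG[k];
  std::vector<double> ld(S);  // log distance per site, for the current t
  std::vector<int> kidx(S);
  for (int i = 0; i < S; ++i) kidx[i] = xcls[i] - 1;
  double inv_dlog = 1.0 / dlog;
  for (int t = 0; t < Tn; ++t) {
    double tp = test_pos[t];
    double la_max = alpha[A - 1];
    // widest window (smallest alpha) bounds all site subsets
    double lo0 = tp - cutoff / alpha[0], hi0 = tp + cutoff / alpha[0];
    int j0 = (int)(std::lower_bound(pos.begin(), pos.end(), lo0) -
                   pos.begin());
    int j1 = (int)(std::upper_bound(pos.begin(), pos.end(), hi0) -
                   pos.begin());
    for (int i = j0; i < j1; ++i) {
      double d = std::fabs(pos[i] - tp);
      ld[i] = (d < 0.5) ? -745.0 : std::log(d);  // exp(-745) underflows
    }
    (void)la_max;
    double best = 0.0, best_a = NA_REAL;
    for (int a = 0; a < A; ++a) {
      double al = alpha[a];
      double la = std::log(al);
      double lo = tp - cutoff / al, hi = tp + cutoff / al;
      int i0 = (a == 0) ? j0
                        : (int)(std::lower_bound(pos.begin() + j0,
                                                 pos.begin() + j1, lo) -
                                pos.begin());
      int i1 = (a == 0) ? j1
                        : (int)(std::upper_bound(pos.begin() + i0,
                                                 pos.begin() + j1, hi) -
                                pos.begin());
      if (i0 >= i1) continue;
      double sum = 0.0;
      double off = (la - log_u0) * inv_dlog;
      for (int i = i0; i < i1; ++i) {
        double bf = ld[i] * inv_dlog + off;
        int bin = (bf <= 0.0) ? 0
                              : (bf >= nb - 1 ? nb - 1 : (int)(bf + 0.5));
        sum += net[(size_t)bin * K + kidx[i]];
      }
      if (sum > best) { best = sum; best_a = al; }
    }
    clr[t] = 2.0 * best;
    ahat[t] = best_a;
  }
  return List::create(_["position"] = test_pos, _["clr"] = clr,
                      _["alpha"] = ahat);
}

// [[Rcpp::export]]
List balance_scan_cpp(NumericVector pos, IntegerVector xcls, NumericVector G,
                      IntegerVector win_first, IntegerVector win_last,
                      NumericVector center, NumericMatrix fB,
                      NumericVector x_grid, NumericVector A_grid, double r) {
  int W = win_first.size();
  int nx = x_grid.size(), nA = A_grid.size();
  NumericVector clr(W), xhat(W), Ahat(W);
  for (int w = 0; w < W; ++w) {
    int i0 = win_first[w] - 1, i1 = win_last[w] - 1;
    int m = i1 - i0 + 1;
    double L0 = 0.0;
    for (int i = i0; i <= i1; ++i) L0 += std::log(G[xcls[i] - 1]);
    double best = L0, bx = NA_REAL, bA = NA_REAL;
    std::vector<double> wt(m);
    for (int a = 0; a < nA; ++a) {
      double A = A_grid[a];
      for (int i = 0; i < m; ++i) {
        double d = std::fabs(pos[i0 + i] - center[w]);
        wt[i] = std::isinf(A) ? 0.0 : std::exp(-A * r * d);
      }
      for (int xi = 0; xi < nx; ++xi) {
        double L1 = 0.0;
        for (int i = 0; i < m; ++i) {
          int k = xcls[i0 + i] - 1;
          L1 += std::log(wt[i] * fB(xi, k) + (1.0 - wt[i]) * G[k]);
        }
        if (L1 > best) { best = L1; bx = x_grid[xi]; bA = A; }
      }
    }
    clr[w] = 2.0 * (best - L0);
    xhat[w] = bx;
    Ahat[w] = bA;
  }
  return List::create(_["center"] = center, _["clr"] = clr,
                      _["xhat"] = xhat, _["Ahat"] = Ahat);
}
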