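#include <Rcpp.h>
#include <algorithm>
#include <vector>
using namespace Rcpp;

// Column-wise association of a sparse non-negative feature matrix with an
// activity vector.  For count features: Spearman rank correlation with a
// two-sided p-value from the t approximation (the standard approximation in
// the presence of ties).  For presence features: two-sided Mann-Whitney U
// comparing activity where the feature is non-zero vs zero, normal
// approximation with tie correction and continuity correction.
//
// Inputs are the dgCMatrix slots plus precomputed quantities of y:
//   y_rank    midranks of activity
//   tie_term  sum over tie groups of y of (t^3 - t)
// [[Rcpp::export(name = ".assoc_columns")]]
DataFrame assoc_columns(IntegerVector Xp, IntegerVector Xi, NumericVector Xx,
                        int n, NumericVector y_rank, double tie_term,
                        bool presence) {
  const int M = Xp.size() - 1;
  NumericVector stat(M), pval(M), prev(M);

  double Sy = 0.0, Sy2 = 0.0;
  for (int i = 0; i < n; ++i) {
    Sy += y_rank[i];
    Sy2 += y_rank[i] * y_rank[i];
  }
  const double mean_r = (n + 1) / 2.0;
  const double vary = Sy2 - n * mean_r * mean_r;

  std::vector<std::pair<double, int> > nz; // (value, row)

  for (int j = 0; j < M; ++j) {
    int lo = Xp[j], hi = Xp[j + 1];
    int nnz = 0;
    nz.clear();
    double Sy_nz = 0.0;
    for (int t = lo; t < hi; ++t) {
      if (Xx[t] != 0.0) {
        if (Xx[t] < 0.0) stop("negative feature value");
        nz.push_back(std::make_pair(Xx[t], Xi[t]));
        Sy_nz += y_rank[Xi[t]];
        ++nnz;
      }
    }
    prev[j] = (double)nnz / n;
    int n0 = n - nnz;
    if (nnz == 0 || n0 == 0) { // constant column (all zero or all present)
      if (!presence && nnz == n) {
        // could still vary among non-zero values; fall through below
      } else {
        stat[j] = NA_REAL;
        pval[j] = 1.0;
        continue;
      }
    }

    if (presence) {
      // Mann-Whitney U, present (non-zero) group vs absent group
      double n1 = nnz;
      double U = Sy_nz - n1 * (n1 + 1) / 2.0;
      stat[j] = U;
      double sigma2 = (n1 * (double)n0 / 12.0) *
                      ((n + 1) - tie_term / ((double)n * (n - 1)));
      if (sigma2 <= 0) {
        pval[j] = 1.0;
        continue;
      }
      double z = U - n1 * (double)n0 / 2.0;
      if (z > 0) z -= 0.5; else if (z < 0) z += 0.5;
      z /= std::sqrt(sigma2);
      double p = 2.0 * R::pnorm(-std::fabs(z), 0.0, 1.0, 1, 0);
      pval[j] = p < 1.0 ? p : 1.0;
    } else {
      // Spearman: midranks of the column (zeros form the lowest tie group)
      std::sort(nz.begin(), nz.end());
      double r0 = (n0 + 1) / 2.0; // midrank of the zero block
      double Srx2 = (double)n0 * r0 * r0;
      double Srxry = r0 * (Sy - Sy_nz);
      size_t a = 0;
      while (a < nz.size()) {
        size_t b = a;
        while (b + 1 < nz.size() && nz[b + 1].first == nz[a].first) ++b;
        double rk = n0 + (double)(a + 1 + b + 1) / 2.0; // midrank of tie group
        for (size_t t = a; t <= b; ++t) {
          Srx2 += rk * rk;
          Srxry += rk * y_rank[nz[t].second];
        }
        a = b + 1;
      }
      double varx = Srx2 - n * mean_r * mean_r;
      if (varx <= 1e-9 || vary <= 1e-9) {
        stat[j] = NA_REAL;
        pval[j] = 1.0;
        continue;
      }
      double rho = (Srxry - n * mean_r * mean_r) / std::sqrt(varx * vary);
      if (rho > 1.0) rho = 1.0;
      if (rho < -1.0) rho = -1.0;
      stat[j] = rho;
      if (1.0 - rho * rho < 1e-15) {
        pval[j] = 0.0;
      } else {
        double tt = rho * std::sqrt((n - 2) / (1.0 - rho * rho));
        pval[j] = 2.0 * R::pt(-std::fabs(tt), n - 2, 1, 0);
      }
    }
  }
  return DataFrame::create(_["statistic"] = stat, _["p"] = pval,
                           _["prevalence"] = prev);
}
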