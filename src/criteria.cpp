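#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Weighted-sum variance criterion for a swarm of candidate difficulty vectors.
//
// Each row of B is one candidate vector of item difficulties packed as
// (unique-1, common, unique-2).  Form 1 holds items [0, n1+nc), form 2 holds
// items [n1, n1+nc+n2); the common block belongs to both.  A criterion
// component j is a target ability theta[j] with weight w[j] attached to one of
// the two forms, and the criterion is sum_j w[j] / TIF_form(j)(theta[j]).
//
// With the grid and discriminations fixed for a whole optimization run,
// exp(-a_i * theta_j) is precomputed once, so evaluating one candidate needs a
// single exp per item plus multiply/divide work: p(1-p) = u / (1+u)^2 with
// u = exp(a_i (b_i - theta_j)).
// [[Rcpp::export]]
NumericVector crit_eval_swarm_cpp(NumericMatrix B, NumericVector a,
                                  NumericVector theta, NumericVector w,
                                  IntegerVector form, int n1, int nc, int n2) {
  const int P = B.nrow();
  const int n = B.ncol();
  const int m = theta.size();
  if (n != n1 + nc + n2)
    stop("difficulty vector length does not match n1 + nc + n2");
  if (w.size() != m || form.size() != m)
    stop("theta, w, form must have equal length");
  if (a.size() != n)
    stop("'a' must have one entry per item");

  std::vector<double> E((size_t)n * m);
  for (int i = 0; i < n; ++i) {
    const double ai = a[i];
    for (int j = 0; j < m; ++j)
      E[(size_t)i * m + j] = std::exp(-ai * theta[j]);
  }

  NumericVector out(P);
  std::vector<double> g(n), a2(n);
  for (int i = 0; i < n; ++i) a2[i] = a[i] * a[i];

  for (int p = 0; p < P; ++p) {
    for (int i = 0; i < n; ++i) g[i] = std::exp(a[i] * B(p, i));
    double val = 0.0;
    for (int j = 0; j < m; ++j) {
      const int lo = (form[j] == 1) ? 0 : n1;
      const int hi = (form[j] == 1) ? (n1 + nc) : n;
      double tif = 0.0;
      for (int i = lo; i < hi; ++i) {
        const double u = E[(size_t)i * m + j] * g[i];
        double pq;
        if (u > 1e100) {
          pq = 1.0 / u;            // avoids (1+u)^2 overflow; p(1-p) ~ 1/u
        } else {
          const double d = 1.0 + u;
          pq = u / (d * d);
        }
        tif += a2[i] * pq;
      }
      val += w[j] / tif;
    }
    out[p] = val;
  }
  return out;
}
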