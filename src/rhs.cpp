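#include <Rcpp.h>
using namespace Rcpp;

// Compiled evaluator for the flattened TXTL network. Mirrors the reference R
// implementation in network.R exactly; reaction kinds:
//   1 bimolecular  k*[i1]*[i2]
//   2 unimolecular k*[i1]
//   3 elongation   k*[i1]*max(pool,0)/(K+max(pool,0))   (pool at i2)
//   4 toxin-gated  k*(1+tanh(tox-thr))*[i1]
//   5 constant     k

// [[Rcpp::export]]
NumericVector rhs_core(NumericVector y, IntegerVector kind, NumericVector k,
                       IntegerVector i1, IntegerVector i2, NumericVector satK,
                       int tox_idx, double thr, int n_species,
                       IntegerVector trip_r, IntegerVector trip_s,
                       NumericVector trip_v) {
  const int nr = kind.size();
  std::vector<double> rate(nr);
  const double tox = y[tox_idx - 1];
  for (int j = 0; j < nr; ++j) {
    double v = 0.0;
    switch (kind[j]) {
    case 1: v = k[j] * y[i1[j] - 1] * y[i2[j] - 1]; break;
    case 2: v = k[j] * y[i1[j] - 1]; break;
    case 3: {
      double p = y[i2[j] - 1];
      if (p < 0.0) p = 0.0;
      v = k[j] * y[i1[j] - 1] * p / (satK[j] + p);
      break;
    }
    case 4: v = k[j] * (1.0 + std::tanh(tox - thr)) * y[i1[j] - 1]; break;
    default: v = k[j]; break;
    }
    rate[j] = v;
  }
  NumericVector dy(n_species);
  const int nt = trip_r.size();
  for (int t = 0; t < nt; ++t)
    dy[trip_s[t] - 1] += trip_v[t] * rate[trip_r[t] - 1];
  return dy;
}
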