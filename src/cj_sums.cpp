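#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Core numerics of the direct multifractal estimator: for each bin size L
// and each exponent q, the two q-mass sums whose log-log slopes give f(q)
// and alpha(q):
//   f_num(q, L) = sum_i mu_i ln mu_i,   a_num(q, L) = sum_i mu_i ln P_i,
// with mu_i = P_i^q / sum_j P_j^q computed in the log domain with
// max-subtraction so |q| up to 200 neither overflows nor underflows.
// Zero-proportion bins contribute zero mass for q > 0; for q <= 0 they make
// the scale unusable and the entry is NA (callers drop it, never floor it).
//
// [[Rcpp::export]]
List cj_scale_sums(NumericVector u, IntegerVector scales, NumericVector q) {
  const int n = u.size(), ns = scales.size(), nq = q.size();
  NumericMatrix f_num(nq, ns), a_num(nq, ns);

  for (int s = 0; s < ns; ++s) {
    const int L = scales[s];
    const int nbins = n / L;
    std::vector<double> logP;
    logP.reserve(nbins);
    double tot = 0.0;
    std::vector<double> sums(nbins);
    for (int b = 0; b < nbins; ++b) {
      double acc = 0.0;
      const int off = b * L;
      for (int k = 0; k < L; ++k) acc += u[off + k];
      sums[b] = acc;
      tot += acc;
    }
    bool has_zero = false;
    for (int b = 0; b < nbins; ++b) {
      if (sums[b] > 0.0) logP.push_back(std::log(sums[b] / tot));
      else has_zero = true;
    }
    const int np = (int)logP.size();
    for (int j = 0; j < nq; ++j) {
      const double qj = q[j];
      if (qj <= 0.0 && has_zero) {
        f_num(j, s) = NA_REAL;
        a_num(j, s) = NA_REAL;
        continue;
      }
      double mx = R_NegInf;
      for (int b = 0; b < np; ++b) {
        const double lw = qj * logP[b];
        if (lw > mx) mx = lw;
      }
      double tw = 0.0;
      for (int b = 0; b < np; ++b) tw += std::exp(qj * logP[b] - mx);
      const double ltw = std::log(tw);
      double fs = 0.0, as = 0.0;
      for (int b = 0; b < np; ++b) {
        const double lmu = qj * logP[b] - mx - ltw;
        const double mu = std::exp(lmu);
        if (mu > 0.0) {
          fs += mu * lmu;
          as += mu * logP[b];
        }
      }
      f_num(j, s) = fs;
      a_num(j, s) = as;
    }
  }
  return List::create(_["f_num"] = f_num, _["a_num"] = a_num);
}
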