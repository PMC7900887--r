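#include <Rcpp.h>
using namespace Rcpp;

// One EM step for the two-population admixture genotype likelihood:
//   theta_il = q_i f1_l + (1 - q_i) f2_l
//   ll = sum_il g_il log(theta_il) + (2 - g_il) log(1 - theta_il)
// Missing calls (NA) contribute nothing. Returns the updated q, f1, f2
// and the log-likelihood of the *incoming* parameters. Mirrors the
// reference implementation admix_em_step_r().
// [[Rcpp::export(name = ".admix_em_step_cpp")]]
List admix_em_step_cpp(const IntegerMatrix& G, const NumericVector& q,
                       const NumericVector& f1, const NumericVector& f2) {
  const int n = G.nrow(), m = G.ncol();
  NumericVector num_q(n), den_q(n), q_new(n), f1_new(m), f2_new(m);
  const double eps = 1e-6;
  double ll = 0.0;
  for (int l = 0; l < m; ++l) {
    const double f1l = f1[l], f2l = f2[l], df = f1l - f2l;
    double ca1 = 0.0, cb1 = 0.0, ca2 = 0.0, cb2 = 0.0;
    for (int i = 0; i < n; ++i) {
      const int g = G(i, l);
      if (g == NA_INTEGER) continue;
      const double qi = q[i];
      const double th = f2l + qi * df;
      double a1 = 0.0, b1 = 0.0;   // expected pop-1 allele attributions
      if (g == 0) {
        b1 = 2.0 * qi * (1.0 - f1l) / (1.0 - th);
        ll += 2.0 * std::log1p(-th);
      } else if (g == 2) {
        a1 = 2.0 * qi * f1l / th;
        ll += 2.0 * std::log(th);
      } else {
        a1 = qi * f1l / th;
        b1 = qi * (1.0 - f1l) / (1.0 - th);
        ll += std::log(th) + std::log1p(-th);
      }
      num_q[i] += a1 + b1;
      den_q[i] += 2.0;
      ca1 += a1; cb1 += b1;
      ca2 += g - a1; cb2 += (2 - g) - b1;
    }
    double v1 = (ca1 + cb1) > 0 ? ca1 / (ca1 + cb1) : 0.5;
    double v2 = (ca2 + cb2) > 0 ? ca2 / (ca2 + cb2) : 0.5;
    f1_new[l] = std::min(std::max(v1, eps), 1.0 - eps);
    f2_new[l] = std::min(std::max(v2, eps), 1.0 - eps);
  }
  for (int i = 0; i < n; ++i)
    q_new[i] = den_q[i] > 0 ? num_q[i] / den_q[i] : 0.5;
  return List::create(_["q"] = q_new, _["f1"] = f1_new, _["f2"] = f2_new,
                      _["ll"] = ll);
}
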