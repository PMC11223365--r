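#include <Rcpp.h>
#include <cmath>
#include <vector>

// Exhaustive maximisation of the two-locus multinomial log-likelihood over
// the regular grid {0, 1/steps, ..., 1}^4 restricted to the simplex.
//
// The 9-class log-likelihood decomposes as
//   sum_i e_i log f_i + n_dh log(2 f1 f4 + 2 f2 f3) + const,
// where e_i are the haplotype counts fixed by the 8 phase-unambiguous
// genotype classes and n_dh is the double-heterozygote count. log f_i is a
// table lookup over the grid values, so the inner loop costs one log call
// (for the double-het term) per point.
//
// [[Rcpp::export]]
Rcpp::List grid_search_hapfreq_cpp(Rcpp::NumericVector e_fixed, double n_dh,
                                   int steps) {
  if (steps < 1) Rcpp::stop("steps must be >= 1");
  const double e1 = e_fixed[0], e2 = e_fixed[1], e3 = e_fixed[2],
               e4 = e_fixed[3];
  const int S = steps;
  std::vector<double> lf(S + 1);
  lf[0] = R_NegInf;
  for (int i = 1; i <= S; ++i) lf[i] = std::log((double)i / S);

  double best = R_NegInf;
  int bi = S, bj = 0, bk = 0;
  const double inv = 1.0 / S, inv2 = inv * inv;

  for (int i = 0; i <= S; ++i) {
    if (e1 > 0 && i == 0) continue;
    const double t1 = (e1 > 0) ? e1 * lf[i] : 0.0;
    for (int j = 0; j <= S - i; ++j) {
      if (e2 > 0 && j == 0) continue;
      const double t2 = t1 + ((e2 > 0) ? e2 * lf[j] : 0.0);
      const int kmax = S - i - j;
      for (int k = 0; k <= kmax; ++k) {
        if (e3 > 0 && k == 0) continue;
        const int l = kmax - k;
        if (e4 > 0 && l == 0) continue;
        double s = t2 + ((e3 > 0) ? e3 * lf[k] : 0.0) +
                   ((e4 > 0) ? e4 * lf[l] : 0.0);
        if (n_dh > 0) {
          const double q = ((double)i * l + (double)j * k) * inv2;
          if (q <= 0) continue;
          s += n_dh * (M_LN2 + std::log(q));
        }
        if (s > best) { best = s; bi = i; bj = j; bk = k; }
      }
    }
  }
  Rcpp::NumericVector f =
      Rcpp::NumericVector::create(bi * inv, bj * inv, bk * inv,
                                  (S - bi - bj - bk) * inv);
  return Rcpp::List::create(Rcpp::Named("f") = f,
                            Rcpp::Named("loglik") = best);
}
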