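#include <Rcpp.h>
using namespace Rcpp;

// Sample entropy by direct template counting (Richman & Moorman).
// Both the m- and (m+1)-length counts use the first n-m templates so the
// conditional-probability interpretation A/B holds exactly. r_abs is the
// absolute Chebyshev tolerance (caller scales by SD). Self-matches excluded.
// Returns -log(A/B); R_PosInf when A == 0; NA handling is the caller's job.
// [[Rcpp::export(name = ".sampen_cpp")]]
double sampen_cpp(NumericVector x, int m, double r_abs) {
  const int n = x.size();
  if (n <= m + 1) stop("series length must exceed m + 1");
  const int nt = n - m;  // number of templates considered for both lengths
  const double *p = REAL(x);
  long long A = 0, B = 0;
  for (int i = 0; i < nt - 1; ++i) {
    const double *xi = p + i;
    for (int j = i + 1; j < nt; ++j) {
      const double *xj = p + j;
      bool match = true;
      for (int k = 0; k < m; ++k) {
        if (std::fabs(xi[k] - xj[k]) > r_abs) { match = false; break; }
      }
      if (match) {
        ++B;
        if (std::fabs(xi[m] - xj[m]) <= r_abs) ++A;
      }
    }
  }
  if (B == 0) return R_PosInf;  // no m-matches at all
  if (A == 0) return R_PosInf;
  return -std::log(static_cast<double>(A) / static_cast<double>(B));
}
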