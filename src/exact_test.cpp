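#include <Rcpp.h>
using namespace Rcpp;

// Two-sided conditional exact p-values for paired negative-binomial
// counts.  For each pair (xa, xb), the conditional distribution of the
// first count given the total n = xa + xb is
//   P(K = k | n) ∝ dnbinom(k; r, mua) * dnbinom(n - k; r, mub),
// with r = 1/phi and null means proportional to the effective library
// sizes.  The mass is accumulated with the ratio recurrence
//   f(k+1)/f(k) = ((k + r)(n - k)) / ((k + 1)(n - k - 1 + r)) * q,
//   q = mua (mub + r) / ((mua + r) mub),
// rescaling on overflow, so no transcendental calls are needed inside
// the loop.  The p-value doubles the smaller tail (tails include the
// observed point) and is capped at 1.
// [[Rcpp::export(name = ".exactNbPvec")]]
NumericVector exactNbPvec(IntegerVector xa, IntegerVector xb,
                          double na, double nb, double phi) {
  const int m = xa.size();
  NumericVector out(m);
  const double r = 1.0 / phi;
  for (int i = 0; i < m; ++i) {
    const double a = xa[i], b = xb[i];
    const double n = a + b;
    if (n == 0) { out[i] = 1.0; continue; }
    const double pihat = n / (na + nb);
    const double mua = pihat * na, mub = pihat * nb;
    const double q = (mua * (mub + r)) / ((mua + r) * mub);
    double v = 1.0;          // f(k) relative to f(0)
    // accumulate both tails directly (deriving one tail from the
    // total cancels catastrophically deep in the tail)
    double total = 0.0, low = 0.0, high = 0.0;
    const double big = 1e290, inv = 1e-290;
    for (double k = 0.0; k <= n; k += 1.0) {
      total += v;
      if (k <= a) low += v;
      if (k >= a) high += v;
      if (k < n) {
        v *= ((k + r) * (n - k)) / ((k + 1.0) * (n - k - 1.0 + r)) * q;
        if (v > big) { v *= inv; total *= inv; low *= inv; high *= inv; }
      }
    }
    double p = 2.0 * std::min(low, high) / total;
    out[i] = p > 1.0 ? 1.0 : p;
  }
  return out;
}
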