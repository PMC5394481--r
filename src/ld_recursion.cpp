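#include <Rcpp.h>
using namespace Rcpp;

// Compound-Poisson (Panjer-type) recursion for the Lea-Coulson mutant-count
// distribution, together with first and second derivatives with respect to m.
//
//   p_0 = exp(-m * (1 - q_0))
//   p_n = (m / n) * sum_{j=1}^{n} j * q_j * p_{n-j}
//
// Derivatives follow by differentiating the recursion:
//   d_0 = -(1 - q_0) p_0,          h_0 = (1 - q_0)^2 p_0
//   d_n = (1/n) S_p + (m/n) S_d,   h_n = (2/n) S_d + (m/n) S_h
// where S_x = sum_{j=1}^{n} j q_j x_{n-j}.
//
// q is the clone-size pmf q_0..q_J; coefficients beyond J are treated as 0,
// which leaves p_0..p_J exact (p_n depends only on q_0..q_n).
//
// [[Rcpp::export]]
NumericMatrix ld_panjer_cpp(double m, NumericVector q, int n_max, int order) {
  if (m < 0) stop("m must be >= 0");
  if (n_max < 0) stop("n_max must be >= 0");
  if (order < 0 || order > 2) stop("order must be 0, 1 or 2");
  const int J = q.size() - 1;  // highest tabulated clone size
  if (J < 0) stop("clone-size pmf is empty");

  NumericMatrix out(n_max + 1, order + 1);
  std::vector<double> p(n_max + 1, 0.0), d, h;
  const double a = 1.0 - q[0];

  p[0] = std::exp(-m * a);
  if (order >= 1) { d.assign(n_max + 1, 0.0); d[0] = -a * p[0]; }
  if (order >= 2) { h.assign(n_max + 1, 0.0); h[0] = a * a * p[0]; }

  for (int n = 1; n <= n_max; ++n) {
    const int jt = std::min(n, J);
    double Sp = 0.0, Sd = 0.0, Sh = 0.0;
    for (int j = 1; j <= jt; ++j) {
      const double jq = j * q[j];
      if (jq == 0.0) continue;
      Sp += jq * p[n - j];
      if (order >= 1) Sd += jq * d[n - j];
      if (order >= 2) Sh += jq * h[n - j];
    }
    p[n] = m / n * Sp;
    if (order >= 1) d[n] = Sp / n + m / n * Sd;
    if (order >= 2) h[n] = 2.0 / n * Sd + m / n * Sh;
  }

  for (int n = 0; n <= n_max; ++n) {
    out(n, 0) = p[n];
    if (order >= 1) out(n, 1) = d[n];
    if (order >= 2) out(n, 2) = h[n];
  }
  return out;
}
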