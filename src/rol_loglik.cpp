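#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Exploded (rank-ordered) logit log-likelihood for three-alternative
// rankings with an optional normal random effect on the status-quo
// alternative, integrated by Gauss-Hermite quadrature.
//
// X:      (3 * n_rec) x p coded matrix, rows of each record sorted by rank
//         (first row = top-ranked alternative).
// resp:   0-based respondent index per record (length n_rec).
// sq:     status-quo indicator per row (length 3 * n_rec).
// z, w:   quadrature nodes and weights, w summing to 1 (single node z = 0,
//         w = 1 reduces exactly to the plain exploded logit).
// theta:  c(beta[p], log_sigma) when re is true, else beta[p].
//
// Returns list(loglik, grad) with grad on the same parameterisation.
// [[Rcpp::export]]
List rol_loglik_cpp(const NumericMatrix& X, const IntegerVector& resp,
                    const NumericVector& sq, int n_resp,
                    const NumericVector& theta,
                    const NumericVector& z, const NumericVector& w,
                    bool re, bool want_grad) {
  const int p = X.ncol();
  const int n_rows = X.nrow();
  const int n_rec = n_rows / 3;
  const int K = z.size();
  const double sigma = re ? std::exp(theta[p]) : 0.0;

  std::vector<double> base_u(n_rows);
  for (int i = 0; i < n_rows; ++i) {
    double u = 0.0;
    for (int j = 0; j < p; ++j) u += X(i, j) * theta[j];
    if (!std::isfinite(u)) stop("non-finite utility encountered");
    base_u[i] = u;
  }

  NumericMatrix lq(n_resp, K);
  std::vector<double> b(K);
  for (int k = 0; k < K; ++k) b[k] = M_SQRT2 * sigma * z[k];

  for (int k = 0; k < K; ++k) {
    for (int r = 0; r < n_rec; ++r) {
      const int i0 = 3 * r;
      const double u1 = base_u[i0]     + b[k] * sq[i0];
      const double u2 = base_u[i0 + 1] + b[k] * sq[i0 + 1];
      const double u3 = base_u[i0 + 2] + b[k] * sq[i0 + 2];
      double m = std::max(u1, std::max(u2, u3));
      const double l3 = m + std::log(std::exp(u1 - m) + std::exp(u2 - m) +
                                     std::exp(u3 - m));
      m = std::max(u2, u3);
      const double l2 = m + std::log(std::exp(u2 - m) + std::exp(u3 - m));
      lq(resp[r], k) += u1 + u2 - l3 - l2;
    }
  }

  // mix over nodes per respondent; keep posterior node weights for the grad
  double loglik = 0.0;
  NumericMatrix a(n_resp, K);
  for (int i = 0; i < n_resp; ++i) {
    double m = lq(i, 0);
    for (int k = 1; k < K; ++k) m = std::max(m, lq(i, k));
    double s = 0.0;
    for (int k = 0; k < K; ++k) s += w[k] * std::exp(lq(i, k) - m);
    loglik += m + std::log(s);
    if (want_grad) {
      for (int k = 0; k < K; ++k) a(i, k) = w[k] * std::exp(lq(i, k) - m) / s;
    }
  }

  NumericVector grad(re ? p + 1 : p);
  if (want_grad) {
    for (int k = 0; k < K; ++k) {
      for (int r = 0; r < n_rec; ++r) {
        const int i0 = 3 * r;
        const double u1 = base_u[i0]     + b[k] * sq[i0];
        const double u2 = base_u[i0 + 1] + b[k] * sq[i0 + 1];
        const double u3 = base_u[i0 + 2] + b[k] * sq[i0 + 2];
        double m = std::max(u1, std::max(u2, u3));
        const double e1 = std::exp(u1 - m), e2 = std::exp(u2 - m),
                     e3 = std::exp(u3 - m);
        const double s3 = e1 + e2 + e3;
        const double p1 = e1 / s3, p2 = e2 / s3, p3 = e3 / s3;
        double m2 = std::max(u2, u3);
        const double f2 = std::exp(u2 - m2), f3 = std::exp(u3 - m2);
        const double q2 = f2 / (f2 + f3), q3 = f3 / (f2 + f3);
        const double g1 = 1.0 - p1;
        const double g2 = 1.0 - p2 - q2;
        const double g3 = -p3 - q3;
        const double ar = a(resp[r], k);
        for (int j = 0; j < p; ++j) {
          grad[j] += ar * (g1 * X(i0, j) + g2 * X(i0 + 1, j) +
                           g3 * X(i0 + 2, j));
        }
        if (re) {
          const double gs = g1 * sq[i0] + g2 * sq[i0 + 1] + g3 * sq[i0 + 2];
          grad[p] += ar * gs * b[k];   // d b_k / d log_sigma = b_k
        }
      }
    }
  }
  return List::create(_["loglik"] = loglik, _["grad"] = grad);
}
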