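#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double logsumexp(const double *v, int n) {
  double m = v[0];
  for (int i = 1; i < n; ++i) if (v[i] > m) m = v[i];
  if (!std::isfinite(m)) return m;
  double s = 0.0;
  for (int i = 0; i < n; ++i) s += std::exp(v[i] - m);
  return m + std::log(s);
}

// Forward recursion in log space. logemit is L x K (0 for missing sites),
// logpi length K, logP is K x K (row = from, col = to).
// [[Rcpp::export]]
double hmm_forward_loglik(NumericMatrix logemit, NumericVector logpi,
                          NumericMatrix logP) {
  const int L = logemit.nrow(), K = logemit.ncol();
  std::vector<double> a(K), anew(K), tmp(K);
  for (int k = 0; k < K; ++k) a[k] = logpi[k] + logemit(0, k);
  for (int l = 1; l < L; ++l) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = a[j] + logP(j, k);
      anew[k] = logsumexp(tmp.data(), K) + logemit(l, k);
    }
    a = anew;
  }
  return logsumexp(a.data(), K);
}

// Forward filtering backward sampling. u is a vector of L uniforms drawn in R
// so that the R RNG governs reproducibility. Returns 1-based states.
// [[Rcpp::export]]
IntegerVector hmm_ffbs(NumericMatrix logemit, NumericVector logpi,
                       NumericMatrix logP, NumericVector u) {
  const int L = logemit.nrow(), K = logemit.ncol();
  NumericMatrix alpha(L, K);
  std::vector<double> tmp(K);
  for (int k = 0; k < K; ++k) alpha(0, k) = logpi[k] + logemit(0, k);
  for (int l = 1; l < L; ++l) {
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = alpha(l - 1, j) + logP(j, k);
      alpha(l, k) = logsumexp(tmp.data(), K) + logemit(l, k);
    }
  }
  IntegerVector s(L);
  std::vector<double> w(K);
  // sample s_L
  {
    for (int k = 0; k < K; ++k) w[k] = alpha(L - 1, k);
    double lz = logsumexp(w.data(), K);
    double cum = 0.0, target = u[L - 1];
    int pick = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += std::exp(w[k] - lz);
      if (target <= cum) { pick = k; break; }
    }
    s[L - 1] = pick + 1;
  }
  for (int l = L - 2; l >= 0; --l) {
    int nxt = s[l + 1] - 1;
    for (int k = 0; k < K; ++k) w[k] = alpha(l, k) + logP(k, nxt);
    double lz = logsumexp(w.data(), K);
    double cum = 0.0, target = u[l];
    int pick = K - 1;
    for (int k = 0; k < K; ++k) {
      cum += std::exp(w[k] - lz);
      if (target <= cum) { pick = k; break; }
    }
    s[l] = pick + 1;
  }
  return s;
}

// Posterior state marginals by forward-backward, L x K.
// [[Rcpp::export]]
NumericMatrix hmm_state_marginals(NumericMatrix logemit, NumericVector logpi,
                                  NumericMatrix logP) {
  const int L = logemit.nrow(), K = logemit.ncol();
  NumericMatrix alpha(L, K), beta(L, K), out(L, K);
  std::vector<double> tmp(K);
  for (int k = 0; k < K; ++k) alpha(0, k) = logpi[k] + logemit(0, k);
  for (int l = 1; l < L; ++l)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j) tmp[j] = alpha(l - 1, j) + logP(j, k);
      alpha(l, k) = logsumexp(tmp.data(), K) + logemit(l, k);
    }
  for (int k = 0; k < K; ++k) beta(L - 1, k) = 0.0;
  for (int l = L - 2; l >= 0; --l)
    for (int k = 0; k < K; ++k) {
      for (int j = 0; j < K; ++j)
        tmp[j] = logP(k, j) + logemit(l + 1, j) + beta(l + 1, j);
      beta(l, k) = logsumexp(tmp.data(), K);
    }
  for (int l = 0; l < L; ++l) {
    for (int k = 0; k < K; ++k) tmp[k] = alpha(l, k) + beta(l, k);
    double lz = logsumexp(tmp.data(), K);
    for (int k = 0; k < K; ++k) out(l, k) = std::exp(tmp[k] - lz);
  }
  return out;
}

// Coordinate descent for penalized weighted least squares in covariance
// form: minimizes 0.5*b'Ab - (bv - alpha*sx)'b + sum thr_j |b_j| jointly
// with the unpenalized intercept alpha. thr is held fixed (one local-linear
// round); callers re-linearize concave penalties between calls.
// [[Rcpp::export]]
List cd_penwls(NumericMatrix A, NumericVector bv, NumericVector sx,
               double sz, double sw, NumericVector thr,
               NumericVector b0, int max_pass, double tol) {
  const int d = A.ncol();
  std::vector<double> b(b0.begin(), b0.end());
  std::vector<double> Ab(d, 0.0);
  for (int j = 0; j < d; ++j)
    if (b[j] != 0.0)
      for (int i = 0; i < d; ++i) Ab[i] += A(i, j) * b[j];
  double alpha = 0.0;
  for (int pass = 0; pass < max_pass; ++pass) {
    double maxdel = 0.0, sxb = 0.0;
    for (int j = 0; j < d; ++j) sxb += sx[j] * b[j];
    alpha = (sz - sxb) / sw;
    for (int j = 0; j < d; ++j) {
      double cj = bv[j] - alpha * sx[j] - (Ab[j] - A(j, j) * b[j]);
      double t = thr[j];
      double num = cj > t ? cj - t : (cj < -t ? cj + t : 0.0);
      double bn = A(j, j) > 0.0 ? num / A(j, j) : 0.0;
      if (bn != b[j]) {
        double del = bn - b[j];
        for (int i = 0; i < d; ++i) Ab[i] += A(i, j) * del;
        double adel = std::abs(del);
        if (adel > maxdel) maxdel = adel;
        b[j] = bn;
      }
    }
    if (maxdel < tol) break;
  }
  double sxb = 0.0;
  for (int j = 0; j < d; ++j) sxb += sx[j] * b[j];
  alpha = (sz - sxb) / sw;
  return List::create(Rcpp::Named("alpha") = alpha,
                      Rcpp::Named("b") = NumericVector(b.begin(), b.end()));
}
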