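// Adaptive Cash-Karp Runge-Kutta integration of the state-dependent
// speciation-extinction (BiSSE/MuSSE) extinction/data ODEs along a branch.
// State vector y = (E_1..E_k, D_1..D_k); time runs from the branch's
// child end towards its parent end.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static void sse_deriv(int k, const double* y, double* dy,
                      const double* lam, const double* mu,
                      const double* Q /* row-major k*k */) {
  const double* E = y;
  const double* D = y + k;
  for (int i = 0; i < k; ++i) {
    double qii = -Q[i * k + i];  // total transition rate out of state i
    double sumE = 0.0, sumD = 0.0;
    for (int j = 0; j < k; ++j) {
      if (j == i) continue;
      sumE += Q[i * k + j] * E[j];
      sumD += Q[i * k + j] * D[j];
    }
    double tot = lam[i] + mu[i] + qii;
    dy[i] = mu[i] - tot * E[i] + lam[i] * E[i] * E[i] + sumE;
    dy[k + i] = -tot * D[i] + 2.0 * lam[i] * E[i] * D[i] + sumD;
  }
}

// Cash-Karp tableau
static const double b21 = 0.2;
static const double b31 = 3.0 / 40.0, b32 = 9.0 / 40.0;
static const double b41 = 0.3, b42 = -0.9, b43 = 1.2;
static const double b51 = -11.0 / 54.0, b52 = 2.5, b53 = -70.0 / 27.0,
                    b54 = 35.0 / 27.0;
static const double b61 = 1631.0 / 55296.0, b62 = 175.0 / 512.0,
                    b63 = 575.0 / 13824.0, b64 = 44275.0 / 110592.0,
                    b65 = 253.0 / 4096.0;
static const double c1 = 37.0 / 378.0, c3 = 250.0 / 621.0,
                    c4 = 125.0 / 594.0, c6 = 512.0 / 1771.0;
static const double dc1 = c1 - 2825.0 / 27648.0,
                    dc3 = c3 - 18575.0 / 48384.0,
                    dc4 = c4 - 13525.0 / 55296.0,
                    dc5 = -277.0 / 14336.0, dc6 = c6 - 0.25;

// [[Rcpp::export]]
NumericVector sse_branch_cpp(NumericVector y0, double len,
                             NumericVector lambda, NumericVector mu,
                             NumericMatrix Q, double rtol, double atol) {
  const int k = lambda.size();
  const int n = 2 * k;
  if (y0.size() != n) stop("y0 must have length 2k");
  std::vector<double> Qr(k * k);
  for (int i = 0; i < k; ++i)
    for (int j = 0; j < k; ++j) Qr[i * k + j] = Q(i, j);
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(n), k2(n), k3(n), k4(n), k5(n), k6(n), yt(n),
      yerr(n), ynew(n);
  double t = 0.0;
  double h = len > 0 ? len / 10.0 : 0.0;
  const double hmin = len * 1e-14;
  long steps = 0;
  while (t < len) {
    if (++steps > 1000000L) stop("SSE branch integration exceeded step cap");
    if (t + h > len) h = len - t;
    sse_deriv(k, y.data(), k1.data(), lambda.begin(), mu.begin(), Qr.data());
    for (int i = 0; i < n; ++i) yt[i] = y[i] + h * b21 * k1[i];
    sse_deriv(k, yt.data(), k2.data(), lambda.begin(), mu.begin(), Qr.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b31 * k1[i] + b32 * k2[i]);
    sse_deriv(k, yt.data(), k3.data(), lambda.begin(), mu.begin(), Qr.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b41 * k1[i] + b42 * k2[i] + b43 * k3[i]);
    sse_deriv(k, yt.data(), k4.data(), lambda.begin(), mu.begin(), Qr.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b51 * k1[i] + b52 * k2[i] + b53 * k3[i] +
                          b54 * k4[i]);
    sse_deriv(k, yt.data(), k5.data(), lambda.begin(), mu.begin(), Qr.data());
    for (int i = 0; i < n; ++i)
      yt[i] = y[i] + h * (b61 * k1[i] + b62 * k2[i] + b63 * k3[i] +
                          b64 * k4[i] + b65 * k5[i]);
    sse_deriv(k, yt.data(), k6.data(), lambda.begin(), mu.begin(), Qr.data());
    double errmax = 0.0;
    for (int i = 0; i < n; ++i) {
      ynew[i] = y[i] + h * (c1 * k1[i] + c3 * k3[i] + c4 * k4[i] +
                            c6 * k6[i]);
      yerr[i] = h * (dc1 * k1[i] + dc3 * k3[i] + dc4 * k4[i] +
                     dc5 * k5[i] + dc6 * k6[i]);
      double sc = atol + rtol * std::max(std::fabs(y[i]),
                                         std::fabs(ynew[i]));
      double e = std::fabs(yerr[i]) / sc;
      if (e > errmax) errmax = e;
    }
    if (errmax <= 1.0) {
      t += h;
      y = ynew;
      double grow = 0.9 * std::pow(std::max(errmax, 1e-10), -0.2);
      if (grow > 5.0) grow = 5.0;
      h *= grow;
    } else {
      double shrink = 0.9 * std::pow(errmax, -0.25);
      if (shrink < 0.1) shrink = 0.1;
      h *= shrink;
      if (h < hmin) stop("SSE branch integration step underflow");
    }
  }
  return NumericVector(y.begin(), y.end());
}
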