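#include <Rcpp.h>
using namespace Rcpp;

// Unit-variance stationary Gaussian-process recursions for irregular schedules.
// All routines work on the temporal *correlation* matrix R of the process;
// marginal variance and the 2x2 spatial covariance are profiled in R code.

// OU: R is Markov, so R^{-1}-quadratic forms come from the AR(1) innovation
// recursion. Returns log det R and M = V' R^{-1} V for a basis matrix V
// (columns: intercept and coordinates).
// [[Rcpp::export]]
List ou_quadforms_cpp(NumericVector times, double tau, NumericMatrix V) {
  int n = times.size(), m = V.ncol();
  NumericMatrix M(m, m);
  double logdet = 0.0;
  std::vector<double> prev(m), u(m);
  for (int j = 0; j < m; ++j) prev[j] = V(0, j);
  for (int j = 0; j < m; ++j)
    for (int k = 0; k < m; ++k) M(j, k) += prev[j] * prev[k];
  for (int i = 1; i < n; ++i) {
    double rho = std::exp(-(times[i] - times[i - 1]) / tau);
    double s2 = 1.0 - rho * rho;
    if (s2 <= 0) stop("duplicate timestamps give a singular OU correlation");
    logdet += std::log(s2);
    double s = std::sqrt(s2);
    for (int j = 0; j < m; ++j) u[j] = (V(i, j) - rho * prev[j]) / s;
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < m; ++k) M(j, k) += u[j] * u[k];
    for (int j = 0; j < m; ++j) prev[j] = V(i, j);
  }
  return List::create(_["logdet"] = logdet, _["M"] = M);
}

// 2x2 transition matrix of the (position, velocity) state over a gap dt for
// the OUF process with rates l1 = 1/tau_p, l2 = 1/tau_v. Handles the
// confluent (l1 == l2) limit.
static void ouf_transition(double dt, double l1, double l2, double F[2][2]) {
  double d = l2 - l1;
  if (std::fabs(d) > 1e-8 * (l1 + l2)) {
    double e1 = std::exp(-l1 * dt), e2 = std::exp(-l2 * dt);
    F[0][0] = (l2 * e1 - l1 * e2) / d;
    F[0][1] = (e1 - e2) / d;
    F[1][0] = -l1 * l2 * F[0][1];
    F[1][1] = (l2 * e2 - l1 * e1) / d;
  } else {
    double l = 0.5 * (l1 + l2), e = std::exp(-l * dt);
    F[0][0] = e * (1.0 + l * dt);
    F[0][1] = e * dt;
    F[1][0] = -e * l * l * dt;
    F[1][1] = e * (1.0 - l * dt);
  }
}

// Stationary state covariance is diag(1, l1*l2) for unit position variance.
// Q(dt) = Pinf - F Pinf F'.
static void ouf_noise(double l1, double l2, const double F[2][2], double Q[2][2]) {
  double vv = l1 * l2;
  // F Pinf F' with Pinf = diag(1, vv)
  double a = F[0][0] * F[0][0] + vv * F[0][1] * F[0][1];
  double b = F[0][0] * F[1][0] + vv * F[0][1] * F[1][1];
  double c = F[1][0] * F[1][0] + vv * F[1][1] * F[1][1];
  Q[0][0] = 1.0 - a;
  Q[0][1] = Q[1][0] = -b;
  Q[1][1] = vv - c;
  if (Q[0][0] < 0) Q[0][0] = 0;
  if (Q[1][1] < 0) Q[1][1] = 0;
}

// OUF: Kalman filter over the (position, velocity) state with exact position
// observations; same return contract as ou_quadforms_cpp.
// [[Rcpp::export]]
List ouf_quadforms_cpp(NumericVector times, double tau_p, double tau_v,
                       NumericMatrix V) {
  int n = times.size(), m = V.ncol();
  double l1 = 1.0 / tau_p, l2 = 1.0 / tau_v;
  NumericMatrix M(m, m);
  double logdet = 0.0;
  // per-column state means (2 x m), shared covariance (2 x 2)
  std::vector<double> z0(m, 0.0), z1(m, 0.0), e(m);
  double P[2][2] = {{1.0, 0.0}, {0.0, l1 * l2}};
  double F[2][2], Q[2][2];
  for (int i = 0; i < n; ++i) {
    if (i > 0) {
      double dt = times[i] - times[i - 1];
      ouf_transition(dt, l1, l2, F);
      ouf_noise(l1, l2, F, Q);
      for (int j = 0; j < m; ++j) {
        double a = F[0][0] * z0[j] + F[0][1] * z1[j];
        double b = F[1][0] * z0[j] + F[1][1] * z1[j];
        z0[j] = a; z1[j] = b;
      }
      double p00 = F[0][0] * P[0][0] + F[0][1] * P[1][0];
      double p01 = F[0][0] * P[0][1] + F[0][1] * P[1][1];
      double p10 = F[1][0] * P[0][0] + F[1][1] * P[1][0];
      double p11 = F[1][0] * P[0][1] + F[1][1] * P[1][1];
      double n00 = p00 * F[0][0] + p01 * F[0][1] + Q[0][0];
      double n01 = p00 * F[1][0] + p01 * F[1][1] + Q[0][1];
      double n11 = p10 * F[1][0] + p11 * F[1][1] + Q[1][1];
      P[0][0] = n00; P[0][1] = P[1][0] = n01; P[1][1] = n11;
    }
    double S = P[0][0];
    if (S <= 0) stop("singular innovation variance in OUF filter");
    logdet += std::log(S);
    for (int j = 0; j < m; ++j) e[j] = V(i, j) - z0[j];
    for (int j = 0; j < m; ++j)
      for (int k = 0; k < m; ++k) M(j, k) += e[j] * e[k] / S;
    double K0 = P[0][0] / S, K1 = P[1][0] / S;
    for (int j = 0; j < m; ++j) { z0[j] += K0 * e[j]; z1[j] += K1 * e[j]; }
    double r0 = P[0][0], r1 = P[0][1];
    P[0][0] -= K0 * r0; P[0][1] -= K0 * r1;
    P[1][0] = P[0][1];  P[1][1] -= K1 * r1;
  }
  return List::create(_["logdet"] = logdet, _["M"] = M);
}

// Exact OU sample path with unit variance from pre-drawn standard normals.
// [[Rcpp::export]]
NumericVector ou_sim_cpp(NumericVector times, double tau, NumericVector z) {
  int n = times.size();
  NumericVector x(n);
  x[0] = z[0];
  for (int i = 1; i < n; ++i) {
    double rho = std::exp(-(times[i] - times[i - 1]) / tau);
    x[i] = rho * x[i - 1] + std::sqrt(1.0 - rho * rho) * z[i];
  }
  return x;
}

// Exact OUF sample path (unit position variance): exact conditional Gaussian
// transitions of the (position, velocity) state; Z is n x 2 standard normals.
// [[Rcpp::export]]
NumericVector ouf_sim_cpp(NumericVector times, double tau_p, double tau_v,
                          NumericMatrix Z) {
  int n = times.size();
  double l1 = 1.0 / tau_p, l2 = 1.0 / tau_v;
  NumericVector x(n);
  double s0 = Z(0, 0), s1 = std::sqrt(l1 * l2) * Z(0, 1);
  x[0] = s0;
  double F[2][2], Q[2][2];
  for (int i = 1; i < n; ++i) {
    double dt = times[i] - times[i - 1];
    ouf_transition(dt, l1, l2, F);
    ouf_noise(l1, l2, F, Q);
    double a00 = std::sqrt(Q[0][0]);
    double a10 = a00 > 0 ? Q[1][0] / a00 : 0.0;
    double d = Q[1][1] - a10 * a10;
    double a11 = d > 0 ? std::sqrt(d) : 0.0;
    double m0 = F[0][0] * s0 + F[0][1] * s1;
    double m1 = F[1][0] * s0 + F[1][1] * s1;
    s0 = m0 + a00 * Z(i, 0);
    s1 = m1 + a10 * Z(i, 0) + a11 * Z(i, 1);
    x[i] = s0;
  }
  return x;
}
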