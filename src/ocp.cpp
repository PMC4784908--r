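#include <Rcpp.h>
#include <cmath>

// Nondimensional self-replicator with log-volume quadrature.
// State x = (p, r, v), control u = alpha in [0,1]:
//   dp/dt = (1 - r) * E - (1 + p) * mu
//   dr/dt = mu * (u - r)
//   dv/dt = mu,  mu = r * p / (K + p)

static inline void rhs(const double x[3], double u, double E, double K,
                       double out[3]) {
  const double p = x[0], r = x[1];
  const double mu = r * p / (K + p);
  out[0] = (1.0 - r) * E - (1.0 + p) * mu;
  out[1] = mu * (u - r);
  out[2] = mu;
}

// A = d f / d x (3x3, row-major), b = d f / d u
static inline void rhs_jac(const double x[3], double u, double E, double K,
                           double A[9], double b[3]) {
  const double p = x[0], r = x[1];
  const double den = K + p;
  const double mu = r * p / den;
  const double mu_p = r * K / (den * den);
  const double mu_r = p / den;
  A[0] = -mu - (1.0 + p) * mu_p;        // d f0 / d p
  A[1] = -E - (1.0 + p) * mu_r;         // d f0 / d r
  A[2] = 0.0;
  A[3] = mu_p * (u - r);                // d f1 / d p
  A[4] = mu_r * (u - r) - mu;           // d f1 / d r
  A[5] = 0.0;
  A[6] = mu_p;                          // d f2 / d p
  A[7] = mu_r;
  A[8] = 0.0;
  b[0] = 0.0;
  b[1] = mu;
  b[2] = 0.0;
}

static inline void rk4_step(const double x[3], double u, double h,
                            double E, double K, double xn[3],
                            double s2[3], double s3[3], double s4[3],
                            double k1[3], double k2[3], double k3[3],
                            double k4[3]) {
  rhs(x, u, E, K, k1);
  for (int i = 0; i < 3; ++i) s2[i] = x[i] + 0.5 * h * k1[i];
  rhs(s2, u, E, K, k2);
  for (int i = 0; i < 3; ++i) s3[i] = x[i] + 0.5 * h * k2[i];
  rhs(s3, u, E, K, k3);
  for (int i = 0; i < 3; ++i) s4[i] = x[i] + h * k3[i];
  rhs(s4, u, E, K, k4);
  for (int i = 0; i < 3; ++i)
    xn[i] = x[i] + h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);
}

// Forward integration of the discrete dynamics (fixed-step RK4,
// piecewise-constant control). Returns (N+1) x 3 matrix of node states.
// [[Rcpp::export(name = ".ocp_forward")]]
Rcpp::NumericMatrix ocp_forward(Rcpp::NumericVector x0,
                                Rcpp::NumericVector u, double h,
                                double E, double K) {
  const int N = u.size();
  Rcpp::NumericMatrix X(N + 1, 3);
  double x[3] = {x0[0], x0[1], x0.size() > 2 ? x0[2] : 0.0};
  double xn[3], s2[3], s3[3], s4[3], k1[3], k2[3], k3[3], k4[3];
  for (int j = 0; j < 3; ++j) X(0, j) = x[j];
  for (int k = 0; k < N; ++k) {
    rk4_step(x, u[k], h, E, K, xn, s2, s3, s4, k1, k2, k3, k4);
    for (int j = 0; j < 3; ++j) { x[j] = xn[j]; X(k + 1, j) = x[j]; }
  }
  return X;
}

// Objective and exact gradient via the discrete adjoint of the RK4 map.
// J = v_N - w * ((p_N - p_pin)^2 + (r_N - r_pin)^2).
// Returns list(J, grad) with grad = dJ/du (length N).
// [[Rcpp::export(name = ".ocp_obj_grad")]]
Rcpp::List ocp_obj_grad(Rcpp::NumericVector x0, Rcpp::NumericVector u,
                        double h, double E, double K, double w,
                        double p_pin, double r_pin) {
  const int N = u.size();
  // forward pass, store node states
  std::vector<double> Xs(3 * (N + 1));
  {
    double x[3] = {x0[0], x0[1], x0.size() > 2 ? x0[2] : 0.0};
    double xn[3], s2[3], s3[3], s4[3], k1[3], k2[3], k3[3], k4[3];
    for (int j = 0; j < 3; ++j) Xs[j] = x[j];
    for (int k = 0; k < N; ++k) {
      rk4_step(x, u[k], h, E, K, xn, s2, s3, s4, k1, k2, k3, k4);
      for (int j = 0; j < 3; ++j) { x[j] = xn[j]; Xs[3 * (k + 1) + j] = x[j]; }
    }
  }
  const double pN = Xs[3 * N + 0], rN = Xs[3 * N + 1], vN = Xs[3 * N + 2];
  const double J = vN - w * ((pN - p_pin) * (pN - p_pin) +
                             (rN - r_pin) * (rN - r_pin));
  // terminal adjoint
  double lam[3] = {-2.0 * w * (pN - p_pin), -2.0 * w * (rN - r_pin), 1.0};
  Rcpp::NumericVector grad(N);
  double s1[3], s2[3], s3[3], s4[3], k1[3], k2[3], k3[3], k4[3], xn[3];
  double A1[9], A2[9], A3[9], A4[9], b1[3], b2[3], b3[3], b4[3];
  double g1[3], g2[3], g3[3], g4[3], tmp[3];
  for (int k = N - 1; k >= 0; --k) {
    for (int j = 0; j < 3; ++j) s1[j] = Xs[3 * k + j];
    rk4_step(s1, u[k], h, E, K, xn, s2, s3, s4, k1, k2, k3, k4);
    rhs_jac(s1, u[k], E, K, A1, b1);
    rhs_jac(s2, u[k], E, K, A2, b2);
    rhs_jac(s3, u[k], E, K, A3, b3);
    rhs_jac(s4, u[k], E, K, A4, b4);
    // g4 = (h/6) lam
    for (int j = 0; j < 3; ++j) g4[j] = h / 6.0 * lam[j];
    // g3 = (h/3) lam + h * A4^T g4
    for (int j = 0; j < 3; ++j) {
      tmp[j] = A4[0 + j] * g4[0] + A4[3 + j] * g4[1] + A4[6 + j] * g4[2];
      g3[j] = h / 3.0 * lam[j] + h * tmp[j];
    }
    // g2 = (h/3) lam + (h/2) * A3^T g3
    for (int j = 0; j < 3; ++j) {
      tmp[j] = A3[0 + j] * g3[0] + A3[3 + j] * g3[1] + A3[6 + j] * g3[2];
      g2[j] = h / 3.0 * lam[j] + 0.5 * h * tmp[j];
    }
    // g1 = (h/6) lam + (h/2) * A2^T g2
    for (int j = 0; j < 3; ++j) {
      tmp[j] = A2[0 + j] * g2[0] + A2[3 + j] * g2[1] + A2[6 + j] * g2[2];
      g1[j] = h / 6.0 * lam[j] + 0.5 * h * tmp[j];
    }
    grad[k] = b1[0] * g1[0] + b1[1] * g1[1] + b1[2] * g1[2] +
              b2[0] * g2[0] + b2[1] * g2[1] + b2[2] * g2[2] +
              b3[0] * g3[0] + b3[1] * g3[1] + b3[2] * g3[2] +
              b4[0] * g4[0] + b4[1] * g4[1] + b4[2] * g4[2];
    // lam_prev = lam + sum_i A_i^T g_i
    double lam_new[3];
    for (int j = 0; j < 3; ++j) {
      lam_new[j] = lam[j] +
        A1[0 + j] * g1[0] + A1[3 + j] * g1[1] + A1[6 + j] * g1[2] +
        A2[0 + j] * g2[0] + A2[3 + j] * g2[1] + A2[6 + j] * g2[2] +
        A3[0 + j] * g3[0] + A3[3 + j] * g3[1] + A3[6 + j] * g3[2] +
        A4[0 + j] * g4[0] + A4[3 + j] * g4[1] + A4[6 + j] * g4[2];
    }
    for (int j = 0; j < 3; ++j) lam[j] = lam_new[j];
  }
  return Rcpp::List::create(Rcpp::Named("J") = J,
                            Rcpp::Named("grad") = grad);
}

// Defects of a candidate (states, controls) pair against the discrete
// RK4 dynamics map: defect_k = x_{k+1} - Phi(x_k, u_k). Returns N x 3.
// [[Rcpp::export(name = ".ocp_defects")]]
Rcpp::NumericMatrix ocp_defects(Rcpp::NumericMatrix X,
                                Rcpp::NumericVector u, double h,
                                double E, double K) {
  const int N = u.size();
  if (X.nrow() != N + 1 || X.ncol() != 3)
    Rcpp::stop("states must be a (N+1) x 3 matrix");
  Rcpp::NumericMatrix D(N, 3);
  double x[3], xn[3], s2[3], s3[3], s4[3], k1[3], k2[3], k3[3], k4[3];
  for (int k = 0; k < N; ++k) {
    for (int j = 0; j < 3; ++j) x[j] = X(k, j);
    rk4_step(x, u[k], h, E, K, xn, s2, s3, s4, k1, k2, k3, k4);
    for (int j = 0; j < 3; ++j) D(k, j) = X(k + 1, j) - xn[j];
  }
  return D;
}
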