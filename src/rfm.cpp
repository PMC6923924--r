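#include <Rcpp.h>
using namespace Rcpp;

// Steady state of the ribosome flow model with initiation term
// lambda_0 (1 - x_1), interior hopping lambda_j x_j (1 - x_{j+1}) and free
// exit lambda_n x_n (conventions: x_0 == 1, x_{n+1} == 0). The steady state
// solves F(x) = 0 with
//   F_j = lambda_{j-1} x_{j-1} (1 - x_j) - lambda_j x_j (1 - x_{j+1}).
// Single-direction shooting on the flux is ill-conditioned for long chains
// (low-density stretches are unstable backward, jammed stretches forward),
// and plain Newton stalls on the soft mode of a traffic-jam front. We use
// pseudo-transient continuation: linearized implicit Euler steps
// (I/tau - dF/dx) delta = F with an adaptive pseudo-timestep tau, solved by
// the Thomas algorithm on the tridiagonal Jacobian. As tau grows the step
// becomes a Newton step; the RFM fixed point is globally asymptotically
// stable, so small tau always makes progress.

static void rfm_F(const NumericVector& lam, const std::vector<double>& x,
                  std::vector<double>& F) {
  int n = x.size();
  for (int j = 0; j < n; ++j) {
    double xm = (j == 0) ? 1.0 : x[j - 1];
    double xp = (j == n - 1) ? 0.0 : x[j + 1];
    F[j] = lam[j] * xm * (1.0 - x[j]) - lam[j + 1] * x[j] * (1.0 - xp);
  }
}

static double max_abs(const std::vector<double>& v) {
  double m = 0.0;
  for (double a : v) m = std::max(m, std::abs(a));
  return m;
}

// [[Rcpp::export]]
NumericVector cpp_rfm_solve(NumericVector lambda, double tol, int max_iter) {
  int n = lambda.size() - 1;
  if (n < 1) stop("need at least one elongation site");
  double lam_max = 0.0;
  for (double l : lambda) {
    if (!(l > 0.0)) stop("all rates must be positive");
    lam_max = std::max(lam_max, l);
  }
  const double eps = 1e-12;
  std::vector<double> x(n, 0.5), F(n), xn(n), Fn(n);

  // mean-field initial guess: the flux is limited by the tightest link
  // (initiation lambda_0, interior capacity lambda_j/4, exit lambda_n);
  // upstream of the limiting link sites take the high-density root of
  // lambda x (1-x) = J, downstream the low-density root.
  {
    double cap = lambda[0];
    int b = 0;
    for (int j = 1; j < n; ++j)
      if (lambda[j] / 4.0 < cap) { cap = lambda[j] / 4.0; b = j; }
    if (lambda[n] < cap) { cap = lambda[n]; b = n; }
    double J0 = 0.9 * cap;
    for (int j = 0; j < n; ++j) {
      double disc = 1.0 - 4.0 * J0 / lambda[j + 1];
      double s = disc > 0.0 ? std::sqrt(disc) : 0.0;
      x[j] = (j + 1 <= b) ? (1.0 + s) / 2.0 : (1.0 - s) / 2.0;
      x[j] = std::min(1.0 - eps, std::max(eps, x[j]));
    }
  }

  std::vector<double> a(n), b(n), c(n), d(n), cp(n), dp(n), delta(n);
  double tau = 1.0 / lam_max;
  rfm_F(lambda, x, F);
  double resid = max_abs(F);
  int it = 0;
  long total = 0;
  const long budget = (long)max_iter * 2000L;
  while (resid >= tol && total < budget) {
    ++total;
    for (int j = 0; j < n; ++j) {
      double xm = (j == 0) ? 1.0 : x[j - 1];
      double xp = (j == n - 1) ? 0.0 : x[j + 1];
      a[j] = (j == 0) ? 0.0 : -lambda[j] * (1.0 - x[j]);     // -dF_j/dx_{j-1}
      b[j] = 1.0 / tau + lambda[j] * xm + lambda[j + 1] * (1.0 - xp);
      c[j] = (j == n - 1) ? 0.0 : -lambda[j + 1] * x[j];     // -dF_j/dx_{j+1}
      d[j] = F[j];
    }
    // Thomas algorithm for (I/tau - dF/dx) delta = F
    bool singular = false;
    cp[0] = c[0] / b[0];
    dp[0] = d[0] / b[0];
    for (int j = 1; j < n; ++j) {
      double m = b[j] - a[j] * cp[j - 1];
      if (m == 0.0 || !std::isfinite(m)) { singular = true; break; }
      cp[j] = c[j] / m;
      dp[j] = (d[j] - a[j] * dp[j - 1]) / m;
    }
    if (singular) { tau *= 0.25; continue; }
    delta[n - 1] = dp[n - 1];
    for (int j = n - 2; j >= 0; --j) delta[j] = dp[j] - cp[j] * delta[j + 1];

    // projected step: the dynamics are monotone and globally stable, so
    // clamping into (0,1) is safe and avoids step rejection
    for (int j = 0; j < n; ++j) {
      xn[j] = x[j] + delta[j];
      if (xn[j] < eps) xn[j] = eps;
      if (xn[j] > 1.0 - eps) xn[j] = 1.0 - eps;
    }
    rfm_F(lambda, xn, Fn);
    double rn = max_abs(Fn);
    if (!std::isfinite(rn)) { tau *= 0.25; continue; }
    // switched evolution relaxation: pseudo-step inversely proportional to
    // the residual, with bounded growth; becomes a Newton step near the
    // root. A slowly creeping jam front makes the residual stagnate at an
    // almost-steady profile; pushing tau up harder is safe (the linearized
    // implicit step is unconditionally stable for this monotone system) and
    // jumps the front to its resting position.
    double ratio = resid / std::max(rn, 1e-300);
    double grow = (ratio > 0.97 && ratio < 1.03) ? 3.0
                                                 : std::min(ratio, 2.0);
    tau = std::min(std::max(tau * grow, 0.5 / lam_max), 1e10 / lam_max);
    x = xn; F = Fn; resid = rn;
    if ((++it & 255) == 0) Rcpp::checkUserInterrupt();
  }
  if (!(resid < tol))
    stop("RFM steady state did not converge (residual %g)", resid);
  NumericVector out(n);
  for (int j = 0; j < n; ++j) out[j] = x[j];
  out.attr("flux") = lambda[n] * x[n - 1];
  return out;
}
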