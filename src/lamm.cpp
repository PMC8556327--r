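#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Bernoulli function B(x) = x / (exp(x) - 1), evaluated stably.
static inline double bern(double x) {
  double ax = std::fabs(x);
  if (ax < 1e-10) return 1.0 - 0.5 * x;
  if (x > 500.0)  return 0.0;          // x * exp(-x) underflows anyway
  if (x < -500.0) return -x;
  if (x > 0.0)    return x * std::exp(-x) / (1.0 - std::exp(-x));
  return x / (std::expm1(x));
}

// Crank-Nicolson time stepping of the Lamm equation
//   dc/dt = (1/r) d/dr [ r ( D dc/dr - s w^2 r c ) ]
// on a uniform finite-volume grid with exponentially fitted
// (Scharfetter-Gummel) face fluxes and zero total flux at both ends.
// r runs from rm (meniscus) to rb (bottom); cells are [rm + i*h, rm + (i+1)*h].
// Returns a matrix with length(times) rows: the cell-centre concentration
// profile at each requested time (times must be nondecreasing, >= 0).
// [[Rcpp::export(name = ".lamm_core")]]
NumericMatrix lamm_core(int ncell, double rm, double rb, double s, double D,
                        double omega2, NumericVector times, double dt0,
                        double loading) {
  if (ncell < 10) stop("ncell must be >= 10");
  if (D <= 0.0) stop("D must be > 0");
  const int n = ncell;
  const double h = (rb - rm) / n;
  std::vector<double> rc(n), rfL(n), rfR(n);
  for (int i = 0; i < n; ++i) {
    rc[i]  = rm + (i + 0.5) * h;
    rfL[i] = rm + i * h;
    rfR[i] = rm + (i + 1) * h;
  }

  // Spatial operator L (tridiagonal): dc/dt = L c.
  // Interior face i+1/2 (between cells i and i+1):
  //   F = r_f * (D/h) * ( B(-Pe) c_i - B(Pe) c_{i+1} ),  Pe = s w^2 r_f h / D
  // dc_i/dt = -(F_{i+1/2} - F_{i-1/2}) / (r_i h); boundary faces carry F = 0.
  std::vector<double> lo(n, 0.0), di(n, 0.0), up(n, 0.0);
  for (int i = 0; i < n - 1; ++i) {
    double rf = rfR[i];
    double pe = s * omega2 * rf * h / D;
    double g  = rf * D / (h * h);
    double bm = bern(-pe), bp = bern(pe);
    // contribution of face to cell i
    di[i]     += -g * bm / rc[i];
    up[i]     +=  g * bp / rc[i];
    // contribution of face to cell i+1
    lo[i + 1] +=  g * bm / rc[i + 1];
    di[i + 1] += -g * bp / rc[i + 1];
  }

  const int nt = times.size();
  NumericMatrix out(nt, n);
  std::vector<double> c(n, loading), cn(n), rhs(n);
  std::vector<double> al(n), ad(n), au(n), cp(n), dp(n);

  double tcur = 0.0;
  for (int k = 0; k < nt; ++k) {
    double target = times[k];
    if (target < tcur - 1e-9) stop("times must be nondecreasing");
    double span = target - tcur;
    if (span > 1e-12) {
      int nsub = (int)std::ceil(span / dt0);
      if (nsub < 1) nsub = 1;
      double dt = span / nsub;
      // M1 = I - dt/2 L (solve), M2 = I + dt/2 L (multiply)
      for (int i = 0; i < n; ++i) {
        al[i] = -0.5 * dt * lo[i];
        ad[i] = 1.0 - 0.5 * dt * di[i];
        au[i] = -0.5 * dt * up[i];
      }
      // Thomas prefactorization
      cp[0] = au[0] / ad[0];
      for (int i = 1; i < n; ++i)
        cp[i] = au[i] / (ad[i] - al[i] * cp[i - 1]);
      for (int step = 0; step < nsub; ++step) {
        // rhs = M2 c
        rhs[0] = (1.0 + 0.5 * dt * di[0]) * c[0] + 0.5 * dt * up[0] * c[1];
        for (int i = 1; i < n - 1; ++i)
          rhs[i] = 0.5 * dt * lo[i] * c[i - 1] +
                   (1.0 + 0.5 * dt * di[i]) * c[i] +
                   0.5 * dt * up[i] * c[i + 1];
        rhs[n - 1] = 0.5 * dt * lo[n - 1] * c[n - 2] +
                     (1.0 + 0.5 * dt * di[n - 1]) * c[n - 1];
        // Thomas solve
        dp[0] = rhs[0] / ad[0];
        for (int i = 1; i < n; ++i)
          dp[i] = (rhs[i] - al[i] * dp[i - 1]) / (ad[i] - al[i] * cp[i - 1]);
        cn[n - 1] = dp[n - 1];
        for (int i = n - 2; i >= 0; --i)
          cn[i] = dp[i] - cp[i] * cn[i + 1];
        c = cn;
      }
      tcur = target;
    }
    for (int i = 0; i < n; ++i) out(k, i) = c[i];
  }
  return out;
}
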