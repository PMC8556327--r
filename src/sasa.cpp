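#include <Rcpp.h>
#include <cmath>
#include <map>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley accessible surface area.
// xyz: n x 3 coordinates (angstrom); rad: expanded radii r_vdw + probe;
// npoints: test points per atom (deterministic Fibonacci sphere).
// Neighbour search uses uniform spatial binning with cell size equal to the
// largest possible contact distance 2 * max(rad).
// [[Rcpp::export(name = ".sasa_core")]]
NumericVector sasa_core(NumericMatrix xyz, NumericVector rad, int npoints) {
  const int n = xyz.nrow();
  if (n < 1) stop("need at least one atom");
  if (npoints < 12) stop("npoints must be >= 12");

  double rmax = 0.0;
  for (int i = 0; i < n; ++i) if (rad[i] > rmax) rmax = rad[i];
  const double cell = 2.0 * rmax + 1e-9;

  // bin atoms
  std::map<std::tuple<int, int, int>, std::vector<int> > bins;
  std::vector<int> cx(n), cy(n), cz(n);
  for (int i = 0; i < n; ++i) {
    cx[i] = (int)std::floor(xyz(i, 0) / cell);
    cy[i] = (int)std::floor(xyz(i, 1) / cell);
    cz[i] = (int)std::floor(xyz(i, 2) / cell);
    bins[std::make_tuple(cx[i], cy[i], cz[i])].push_back(i);
  }

  // Fibonacci sphere directions
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  std::vector<double> px(npoints), py(npoints), pz(npoints);
  for (int k = 0; k < npoints; ++k) {
    double z = 1.0 - (2.0 * k + 1.0) / npoints;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    px[k] = r * std::cos(ga * k);
    py[k] = r * std::sin(ga * k);
    pz[k] = z;
  }

  NumericVector area(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy)
        for (int dz = -1; dz <= 1; ++dz) {
          auto it = bins.find(std::make_tuple(cx[i] + dx, cy[i] + dy, cz[i] + dz));
          if (it == bins.end()) continue;
          for (int j : it->second) {
            if (j == i) continue;
            double ddx = xyz(j, 0) - xyz(i, 0);
            double ddy = xyz(j, 1) - xyz(i, 1);
            double ddz = xyz(j, 2) - xyz(i, 2);
            double d2 = ddx * ddx + ddy * ddy + ddz * ddz;
            double lim = rad[i] + rad[j];
            if (d2 < lim * lim) nb.push_back(j);
          }
        }
    int nacc = 0;
    const double ri = rad[i];
    for (int k = 0; k < npoints; ++k) {
      double qx = xyz(i, 0) + ri * px[k];
      double qy = xyz(i, 1) + ri * py[k];
      double qz = xyz(i, 2) + ri * pz[k];
      bool buried = false;
      for (int j : nb) {
        double ddx = qx - xyz(j, 0);
        double ddy = qy - xyz(j, 1);
        double ddz = qz - xyz(j, 2);
        if (ddx * ddx + ddy * ddy + ddz * ddz < rad[j] * rad[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++nacc;
    }
    area[i] = 4.0 * M_PI * ri * ri * (double)nacc / npoints;
  }
  return area;
}
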