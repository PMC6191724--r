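#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area.
//
// Each atom is inflated by the probe radius and sampled with a
// deterministic golden-spiral point set; a sample point is accessible if
// it lies outside every neighbouring inflated sphere. Area per atom is
// the accessible fraction of 4*pi*R^2.
//
// [[Rcpp::export(name = ".sasa_shrake_rupley")]]
NumericVector sasa_shrake_rupley(NumericMatrix xyz, NumericVector radii,
                                 double probe, int n_points) {
  const int n = xyz.nrow();
  NumericVector area(n);
  if (n == 0) return area;

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    double zk = 1.0 - 2.0 * (k + 0.5) / n_points;
    double rk = std::sqrt(std::max(0.0, 1.0 - zk * zk));
    double th = golden * k;
    px[k] = rk * std::cos(th);
    py[k] = rk * std::sin(th);
    pz[k] = zk;
  }

  std::vector<double> R(n);
  for (int i = 0; i < n; ++i) R[i] = radii[i] + probe;

  std::vector<int> nbr;
  nbr.reserve(64);
  for (int i = 0; i < n; ++i) {
    const double xi = xyz(i, 0), yi = xyz(i, 1), zi = xyz(i, 2);
    nbr.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      double dx = xyz(j, 0) - xi, dy = xyz(j, 1) - yi, dz = xyz(j, 2) - zi;
      double lim = R[i] + R[j];
      if (dx * dx + dy * dy + dz * dz < lim * lim) nbr.push_back(j);
    }
    int acc = 0;
    for (int k = 0; k < n_points; ++k) {
      const double sx = xi + R[i] * px[k];
      const double sy = yi + R[i] * py[k];
      const double sz = zi + R[i] * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nbr.size(); ++m) {
        const int j = nbr[m];
        double dx = sx - xyz(j, 0), dy = sy - xyz(j, 1), dz = sz - xyz(j, 2);
        if (dx * dx + dy * dy + dz * dz < R[j] * R[j]) {
          buried = true;
          break;
        }
      }
      if (!buried) ++acc;
    }
    area[i] = 4.0 * M_PI * R[i] * R[i] * acc / n_points;
  }
  return area;
}
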