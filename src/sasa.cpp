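#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area. Test points are placed on
// each expanded sphere (vdW radius + probe) by a deterministic golden-section
// spiral; a point is accessible when it lies outside every neighbouring
// expanded sphere. Area = exposed fraction * sphere area.

// [[Rcpp::export]]
NumericVector sasa_shrake_rupley_cpp(NumericMatrix xyz, NumericVector radii,
                                     double probe, int n_points) {
  const int n = xyz.nrow();
  if (n_points < 1) stop("n_points must be >= 1");

  // golden-spiral unit sphere points
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double golden = M_PI * (3.0 - std::sqrt(5.0));
  for (int k = 0; k < n_points; ++k) {
    const double z = 1.0 - 2.0 * (k + 0.5) / n_points;
    const double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    const double th = golden * k;
    px[k] = r * std::cos(th);
    py[k] = r * std::sin(th);
    pz[k] = z;
  }

  std::vector<double> er(n);
  for (int i = 0; i < n; ++i) er[i] = radii[i] + probe;

  NumericVector area(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = xyz(j, 0) - xyz(i, 0);
      const double dy = xyz(j, 1) - xyz(i, 1);
      const double dz = xyz(j, 2) - xyz(i, 2);
      const double cut = er[i] + er[j];
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double qx = xyz(i, 0) + er[i] * px[k];
      const double qy = xyz(i, 1) + er[i] * py[k];
      const double qz = xyz(i, 2) + er[i] * pz[k];
      bool free_pt = true;
      for (int jj : nb) {
        const double dx = qx - xyz(jj, 0);
        const double dy = qy - xyz(jj, 1);
        const double dz = qz - xyz(jj, 2);
        if (dx * dx + dy * dy + dz * dz < er[jj] * er[jj]) { free_pt = false; break; }
      }
      if (free_pt) ++exposed;
    }
    area[i] = 4.0 * M_PI * er[i] * er[i] * exposed / n_points;
  }
  return area;
}
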