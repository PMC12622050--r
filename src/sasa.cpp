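#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Shrake-Rupley solvent-accessible surface area with a deterministic
// golden-spiral point set. Areas in A^2; coords in A.
// [[Rcpp::export]]
NumericVector cpp_shrake_rupley(NumericMatrix coords, NumericVector radii,
                                double probe, int n_points) {
  const int n = coords.nrow();
  if (radii.size() != n) stop("radii length must match number of atoms");
  std::vector<double> px(n_points), py(n_points), pz(n_points);
  const double ga = M_PI * (3.0 - std::sqrt(5.0));
  for (int i = 0; i < n_points; ++i) {
    double z = 1.0 - 2.0 * (i + 0.5) / n_points;
    double r = std::sqrt(std::max(0.0, 1.0 - z * z));
    double phi = ga * i;
    px[i] = r * std::cos(phi);
    py[i] = r * std::sin(phi);
    pz[i] = z;
  }
  NumericVector area(n);
  std::vector<int> nb;
  for (int i = 0; i < n; ++i) {
    const double Ri = radii[i] + probe;
    nb.clear();
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double Rj = radii[j] + probe;
      const double dx = coords(i, 0) - coords(j, 0);
      const double dy = coords(i, 1) - coords(j, 1);
      const double dz = coords(i, 2) - coords(j, 2);
      const double cut = Ri + Rj;
      if (dx * dx + dy * dy + dz * dz < cut * cut) nb.push_back(j);
    }
    int exposed = 0;
    for (int k = 0; k < n_points; ++k) {
      const double x = coords(i, 0) + Ri * px[k];
      const double y = coords(i, 1) + Ri * py[k];
      const double z = coords(i, 2) + Ri * pz[k];
      bool buried = false;
      for (size_t m = 0; m < nb.size(); ++m) {
        const int j = nb[m];
        const double Rj = radii[j] + probe;
        const double dx = x - coords(j, 0);
        const double dy = y - coords(j, 1);
        const double dz = z - coords(j, 2);
        if (dx * dx + dy * dy + dz * dz < Rj * Rj) { buried = true; break; }
      }
      if (!buried) ++exposed;
    }
    area[i] = 4.0 * M_PI * Ri * Ri * (double)exposed / (double)n_points;
  }
  return area;
}
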