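#include <Rcpp.h>
using namespace Rcpp;

// Accumulate point scatterers convolved with a separable Gaussian-modulated
// PSF onto an RF frame grid. Positions in mm; the axial kernel carries the
// carrier (k cycles/mm of depth), so sub-sample positions shift the RF phase.
// [[Rcpp::export]]
NumericMatrix render_rf_cpp(NumericVector ax, NumericVector lat,
                            NumericVector amp, int n_axial, int n_lines,
                            double dz, double dx, double sig_z, double sig_x,
                            double k) {
  NumericMatrix frame(n_axial, n_lines);
  const int hw_z = (int)std::ceil(3.0 * sig_z / dz);
  const int hw_x = (int)std::ceil(3.0 * sig_x / dx);
  const double inv2sz = 1.0 / (2.0 * sig_z * sig_z);
  const double inv2sx = 1.0 / (2.0 * sig_x * sig_x);
  const double two_pi_k = 2.0 * M_PI * k;
  std::vector<double> az(2 * hw_z + 1);
  for (int i = 0; i < ax.size(); ++i) {
    const int iz = (int)std::lround(ax[i] / dz);
    const int ix = (int)std::lround(lat[i] / dx);
    const int z0 = std::max(0, iz - hw_z), z1 = std::min(n_axial - 1, iz + hw_z);
    const int x0 = std::max(0, ix - hw_x), x1 = std::min(n_lines - 1, ix + hw_x);
    if (z0 > z1 || x0 > x1) continue;
    for (int z = z0; z <= z1; ++z) {
      const double uz = z * dz - ax[i];
      az[z - z0] = std::exp(-uz * uz * inv2sz) * std::cos(two_pi_k * uz);
    }
    for (int x = x0; x <= x1; ++x) {
      const double ux = x * dx - lat[i];
      const double w = amp[i] * std::exp(-ux * ux * inv2sx);
      for (int z = z0; z <= z1; ++z) frame(z, x) += w * az[z - z0];
    }
  }
  return frame;
}
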