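#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Raster-scanned image series of Brownian particles observed through a 3D
// Gaussian PSF. Particles live in a periodic box; positions advance by
// Euler-Maruyama steps `substeps` times per raster line, so motion occurs
// during the scan on the line-time clock. Pixel intensities are Poisson
// draws around brightness * PSF plus a constant offset.
//
// pos: n x 3 matrix of particle positions (um), modified in place.
// Returns numeric vector of length nx*ny*nframes, frame-major, row = line.
// [[Rcpp::export]]
NumericVector cpp_scan_brownian(int nx, int ny, int nframes,
                                double px_um,
                                NumericMatrix pos,
                                double step_sd_um, int substeps,
                                double brightness, double offset,
                                double w0, double wz,
                                double box_x, double box_y, double box_z,
                                double cutoff_xy, double cutoff_z,
                                bool add_noise) {
  const int n = pos.nrow();
  const double x0 = (box_x - nx * px_um) / 2.0; // image offset in box
  const double y0 = (box_y - ny * px_um) / 2.0;
  const double zf = box_z / 2.0;                // focal plane
  const double inv_w02 = 2.0 / (w0 * w0);
  const double inv_wz2 = 2.0 / (wz * wz);

  NumericVector out((R_xlen_t)nx * ny * nframes);
  std::vector<double> lambda((size_t)nx * ny);
  RNGScope scope;

  for (int f = 0; f < nframes; ++f) {
    std::fill(lambda.begin(), lambda.end(), offset);
    for (int iy = 0; iy < ny; ++iy) {
      const double ypix = y0 + (iy + 0.5) * px_um;
      for (int s = 0; s < substeps; ++s) {
        // advance all particles by one sub-line Brownian step
        if (step_sd_um > 0.0 && n > 0) {
          for (int p = 0; p < n; ++p) {
            for (int k = 0; k < 3; ++k) {
              double v = pos(p, k) + R::norm_rand() * step_sd_um;
              double L = (k == 0) ? box_x : (k == 1) ? box_y : box_z;
              v -= L * std::floor(v / L); // wrap to [0, L)
              pos(p, k) = v;
            }
          }
        }
        // pixels sampled during this substep
        const int ix_lo = (int)((double)s * nx / substeps);
        const int ix_hi = (int)((double)(s + 1) * nx / substeps);
        for (int p = 0; p < n; ++p) {
          double dy = pos(p, 1) - ypix;
          dy -= box_y * std::round(dy / box_y);
          if (std::fabs(dy) > cutoff_xy) continue;
          double dz = pos(p, 2) - zf;
          dz -= box_z * std::round(dz / box_z);
          if (std::fabs(dz) > cutoff_z) continue;
          const double wy = std::exp(-(dy * dy) * inv_w02 -
                                     (dz * dz) * inv_wz2) * brightness;
          if (wy < 1e-9) continue;
          const double q = std::exp(-2.0 * px_um * px_um * inv_w02);
          double *lam = &lambda[(size_t)iy * nx];
          // contributions from the particle and its periodic x-images
          for (int o = -1; o <= 1; ++o) {
            const double xc = pos(p, 0) - x0 + o * box_x;
            int jlo = (int)std::ceil((xc - cutoff_xy) / px_um - 0.5);
            int jhi = (int)std::floor((xc + cutoff_xy) / px_um - 0.5);
            if (jlo < ix_lo) jlo = ix_lo;
            if (jhi >= ix_hi) jhi = ix_hi - 1;
            if (jlo > jhi) continue;
            // exact Gaussian recurrence: g(x+d) = g(x) * r, r *= q
            const double dx0 = (jlo + 0.5) * px_um - xc;
            double g = wy * std::exp(-dx0 * dx0 * inv_w02);
            double r = std::exp(-px_um * (2.0 * dx0 + px_um) * inv_w02);
            for (int ix = jlo; ix <= jhi; ++ix) {
              lam[ix] += g;
              g *= r;
              r *= q;
            }
          }
        }
      }
    }
    double *dst = &out[(R_xlen_t)f * nx * ny];
    for (size_t i = 0; i < (size_t)nx * ny; ++i) {
      dst[i] = add_noise ? R::rpois(lambda[i]) : lambda[i];
    }
  }
  return out;
}
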