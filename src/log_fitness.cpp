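#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Scale-normalized Laplacian-of-Gaussian response of the image at each
// trace node, with analytic first and second derivatives with respect to
// the node position r (3 physical coordinates) and the caliber sigma.
//
// The kernel width is the effective se^2 = sigma^2 + vox_var, where
// vox_var = (sx sy sz)^{2/3} / 12 is the variance of the voxel footprint:
// the discrete sum point-samples the kernel, and without the footprint
// term the sum diverges like sigma^-3 as sigma -> 0, creating a spurious
// attractor for calibers far below the voxel size.
//
// Kernel (d = voxel center - r, u = |d|^2, a = 1/se^2, v = u * a):
//   K = k0 * a^{3/2} * (3 - v) * exp(-v / 2),   k0 = (2*pi)^{-3/2}
// i.e. -se^2 * Laplacian of a unit-mass Gaussian, so that for a tube with
// Gaussian cross-section of radius t the response is maximized at
// se = t (sigma ~= t for t above the voxel size). The node term is
// vol * sum_m I_m K(l_m - r; se), summed over voxels within trunc_sd * se
// of the node (box clipped to stack).
//
// Derivatives w.r.t. se (delta_ij Kronecker):
//   dK/dr_j        =  k0 a^{5/2} E d_j (5 - v)
//   d2K/dr_i dr_j  =  k0 a^{5/2} E [ a d_i d_j (7 - v) - delta_ij (5 - v) ]
//   dK/dse         = -k0 a^2 E (9 - 8v + v^2)
//   d2K/dse2       =  k0 (a^2/se) E (36 - 57v + 16v^2 - v^3)
//   d2K/dse dr_j   =  k0 a^{5/2} E (d_j/se) (-25 + 12v - v^2)
// chained to sigma via dse/dsigma = sigma/se and
// d2se/dsigma2 = vox_var / se^3.

// [[Rcpp::export(name = ".log_terms_cpp")]]
List log_terms_cpp(NumericVector voxels, IntegerVector dims,
                   NumericVector spacing, NumericVector origin,
                   NumericMatrix pos, NumericVector sigma,
                   double trunc_sd, bool derivs) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double vol = sx * sy * sz;
  const double vox_var = std::pow(vol, 2.0 / 3.0) / 12.0;
  const double k0 = 1.0 / std::pow(2.0 * M_PI, 1.5);
  const int n = pos.nrow();

  NumericVector value(n);
  NumericMatrix grad(derivs ? n : 0, 4);
  NumericMatrix hess(derivs ? n : 0, 16); // row-major 4x4 per node

  for (int q = 0; q < n; ++q) {
    const double rx = pos(q, 0), ry = pos(q, 1), rz = pos(q, 2);
    const double sg = sigma[q];
    const double se = std::sqrt(sg * sg + vox_var);
    const double cs = sg / se;                 // dse/dsigma
    const double cs2 = vox_var / (se * se * se); // d2se/dsigma2
    const double a = 1.0 / (se * se);
    const double rad = trunc_sd * se;
    // voxel index range (1-based voxel i has physical coord origin+(i-1)*s)
    int i0 = (int)std::ceil((rx - origin[0] - rad) / sx);
    int i1 = (int)std::floor((rx - origin[0] + rad) / sx);
    int j0 = (int)std::ceil((ry - origin[1] - rad) / sy);
    int j1 = (int)std::floor((ry - origin[1] + rad) / sy);
    int k0i = (int)std::ceil((rz - origin[2] - rad) / sz);
    int k1 = (int)std::floor((rz - origin[2] + rad) / sz);
    if (i0 < 0) i0 = 0; if (i1 > nx - 1) i1 = nx - 1;
    if (j0 < 0) j0 = 0; if (j1 > ny - 1) j1 = ny - 1;
    if (k0i < 0) k0i = 0; if (k1 > nz - 1) k1 = nz - 1;

    double val = 0;
    double g[4] = {0, 0, 0, 0};
    double H[16] = {0};

    for (int k = k0i; k <= k1; ++k) {
      double dz = origin[2] + k * sz - rz;
      for (int j = j0; j <= j1; ++j) {
        double dy = origin[1] + j * sy - ry;
        for (int i = i0; i <= i1; ++i) {
          double dx = origin[0] + i * sx - rx;
          double u = dx * dx + dy * dy + dz * dz;
          if (u > rad * rad) continue;
          double I = voxels[i + nx * (j + (size_t)ny * k)];
          if (I == 0) continue;
          double v = u * a;
          double E = std::exp(-0.5 * v);
          double a32 = a * std::sqrt(a);   // a^{3/2}
          double a52 = a32 * a;            // a^{5/2}
          double cI = k0 * I;
          val += cI * a32 * (3.0 - v) * E;
          if (derivs) {
            double d[3] = {dx, dy, dz};
            double f1 = cI * a52 * E * (5.0 - v);
            for (int t = 0; t < 3; ++t) g[t] += f1 * d[t];
            double kse = -cI * a * a * E * (9.0 - v * (8.0 - v));
            g[3] += kse * cs;
            double c7 = cI * a52 * E;
            for (int t = 0; t < 3; ++t)
              for (int w = t; w < 3; ++w) {
                double h = c7 * (a * d[t] * d[w] * (7.0 - v) -
                                 (t == w ? (5.0 - v) : 0.0));
                H[4 * t + w] += h;
                if (t != w) H[4 * w + t] += h;
              }
            double fs = cI * a52 * E / se * (-25.0 + v * (12.0 - v)) * cs;
            for (int t = 0; t < 3; ++t) {
              H[4 * t + 3] += fs * d[t];
              H[4 * 3 + t] += fs * d[t];
            }
            H[15] += cI * a * a / se * E *
                     (36.0 - v * (57.0 - v * (16.0 - v))) * cs * cs +
                     kse * cs2;
          }
        }
      }
    }
    value[q] = vol * val;
    if (derivs) {
      for (int t = 0; t < 4; ++t) grad(q, t) = vol * g[t];
      for (int t = 0; t < 16; ++t) hess(q, t) = vol * H[t];
    }
  }

  if (derivs)
    return List::create(_["value"] = value, _["grad"] = grad, _["hess"] = hess);
  return List::create(_["value"] = value);
}
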