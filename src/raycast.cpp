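#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Spherical sweep of rays from a fixed origin through a voxel lattice.
//
// Directions are theta (azimuth, XY-plane) = 0..(n_theta-1) * step_deg and
// phi (polar angle from +z) = 0..(n_phi-1) * step_deg.  Each ray is sampled
// at fixed arc increments of ray_step mm; the sample's containing voxel is
// found by nearest-voxel lookup.  A ray terminates at the first sample whose
// voxel lies outside the sac mask or outside the grid.  The recorded
// thickness is the Euclidean distance (mm) between the first and last sample
// positions whose voxel belongs to the EAT mask, or 0 if none does.
//
// sac/eat are int vectors in R array order (column-major, dims d1,d2,d3);
// spacing/origin/centre are in mm, physical coordinate of voxel (0,0,0)
// being `origin`.
// [[Rcpp::export(name = ".raycast_sweep")]]
NumericMatrix raycast_sweep(IntegerVector sac, IntegerVector eat,
                            IntegerVector dims,
                            NumericVector spacing, NumericVector origin,
                            NumericVector centre,
                            double step_deg, double ray_step) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double sx = spacing[0], sy = spacing[1], sz = spacing[2];
  const double ox = origin[0], oy = origin[1], oz = origin[2];
  const double cx = centre[0], cy = centre[1], cz = centre[2];
  const int n_theta = (int) std::lround(360.0 / step_deg);
  const int n_phi   = (int) std::lround(180.0 / step_deg);
  const double deg2rad = M_PI / 180.0;

  // generous upper bound on ray length: grid diagonal
  const double max_len = std::sqrt(std::pow(d1 * sx, 2) +
                                   std::pow(d2 * sy, 2) +
                                   std::pow(d3 * sz, 2));
  const int max_steps = (int) std::ceil(max_len / ray_step) + 2;

  NumericMatrix field(n_theta, n_phi);
  for (int it = 0; it < n_theta; ++it) {
    const double theta = it * step_deg * deg2rad;
    const double ct = std::cos(theta), st = std::sin(theta);
    for (int ip = 0; ip < n_phi; ++ip) {
      const double phi = ip * step_deg * deg2rad;
      const double sp = std::sin(phi), cp = std::cos(phi);
      const double dx = sp * ct, dy = sp * st, dz = cp;
      double first_s = -1.0, last_s = -1.0;
      for (int k = 0; k < max_steps; ++k) {
        const double s = k * ray_step;
        const double px = cx + s * dx, py = cy + s * dy, pz = cz + s * dz;
        const int i = (int) std::lround((px - ox) / sx);
        const int j = (int) std::lround((py - oy) / sy);
        const int l = (int) std::lround((pz - oz) / sz);
        if (i < 0 || i >= d1 || j < 0 || j >= d2 || l < 0 || l >= d3) break;
        const R_xlen_t idx = (R_xlen_t) i + (R_xlen_t) d1 * (j + (R_xlen_t) d2 * l);
        if (sac[idx] == 0) break;
        if (eat[idx] != 0) {
          if (first_s < 0) first_s = s;
          last_s = s;
        }
      }
      field(it, ip) = (first_s < 0) ? 0.0 : (last_s - first_s);
    }
  }
  return field;
}

// One-dimensional squared-distance transform (lower envelope of parabolas),
// with physical sample spacing w.  f holds squared distances on input.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z,
                 int n, double w) {
  const double INF = 1e30;
  int k = 0;
  v[0] = 0;
  z[0] = -INF;
  z[1] = INF;
  for (int q = 1; q < n; ++q) {
    const double xq = q * w;
    double s;
    while (true) {
      const double xv = v[k] * w;
      s = ((f[q] + xq * xq) - (f[v[k]] + xv * xv)) / (2 * xq - 2 * xv);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = INF;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    const double xq = q * w;
    while (z[k + 1] < xq) ++k;
    const double xv = v[k] * w;
    d[q] = (xq - xv) * (xq - xv) + f[v[k]];
  }
}

// Exact Euclidean distance transform of a binary mask with anisotropic voxel
// spacing (mm).  Returns, for every foreground voxel, the distance to the
// nearest background voxel centre; background voxels get 0.
// [[Rcpp::export(name = ".edt_anisotropic")]]
NumericVector edt_anisotropic(IntegerVector mask, IntegerVector dims,
                              NumericVector spacing) {
  const int d1 = dims[0], d2 = dims[1], d3 = dims[2];
  const double INF = 1e30;
  const R_xlen_t n = (R_xlen_t) d1 * d2 * d3;
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) out[i] = (mask[i] != 0) ? INF : 0.0;

  const int nmax = std::max(d1, std::max(d2, d3));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // pass along axis 1
  for (int l = 0; l < d3; ++l)
    for (int j = 0; j < d2; ++j) {
      const R_xlen_t base = (R_xlen_t) d1 * (j + (R_xlen_t) d2 * l);
      for (int i = 0; i < d1; ++i) f[i] = out[base + i];
      dt1d(f, d, v, z, d1, spacing[0]);
      for (int i = 0; i < d1; ++i) out[base + i] = d[i];
    }
  // pass along axis 2
  for (int l = 0; l < d3; ++l)
    for (int i = 0; i < d1; ++i) {
      const R_xlen_t base = (R_xlen_t) i + (R_xlen_t) d1 * d2 * (R_xlen_t) l;
      for (int j = 0; j < d2; ++j) f[j] = out[base + (R_xlen_t) d1 * j];
      dt1d(f, d, v, z, d2, spacing[1]);
      for (int j = 0; j < d2; ++j) out[base + (R_xlen_t) d1 * j] = d[j];
    }
  // pass along axis 3
  const R_xlen_t plane = (R_xlen_t) d1 * d2;
  for (int j = 0; j < d2; ++j)
    for (int i = 0; i < d1; ++i) {
      const R_xlen_t base = (R_xlen_t) i + (R_xlen_t) d1 * j;
      for (int l = 0; l < d3; ++l) f[l] = out[base + plane * l];
      dt1d(f, d, v, z, d3, spacing[2]);
      for (int l = 0; l < d3; ++l) out[base + plane * l] = d[l];
    }

  for (R_xlen_t i = 0; i < n; ++i) out[i] = std::sqrt(out[i]);
  out.attr("dim") = dims;
  return out;
}
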