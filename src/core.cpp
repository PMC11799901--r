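// Numerical kernels: trilinear sampling, rigid/affine resampling, Siddon
// voxel traversal (water-equivalent path length), the divergent-beam dose
// kernel, 3D local gamma (pruned search and exhaustive oracle), and 3D
// connected-component labelling.  Geometry convention throughout: voxel
// centers, 0-based indices, world = origin + axes %*% (index * spacing),
// axes orthonormal and stored column-major.
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>
#include <queue>
using namespace Rcpp;

struct Grid {
  const double* v;
  int nx, ny, nz;
  double o[3];   // origin (world, mm)
  double s[3];   // spacing (mm)
  double a[9];   // direction matrix, column-major; column c = axis of index c

  inline void w2i(const double* p, double* x) const {
    double d0 = p[0] - o[0], d1 = p[1] - o[1], d2 = p[2] - o[2];
    x[0] = (a[0] * d0 + a[1] * d1 + a[2] * d2) / s[0];
    x[1] = (a[3] * d0 + a[4] * d1 + a[5] * d2) / s[1];
    x[2] = (a[6] * d0 + a[7] * d1 + a[8] * d2) / s[2];
  }
  inline void i2w(const double* x, double* p) const {
    double w0 = x[0] * s[0], w1 = x[1] * s[1], w2 = x[2] * s[2];
    p[0] = o[0] + a[0] * w0 + a[3] * w1 + a[6] * w2;
    p[1] = o[1] + a[1] * w0 + a[4] * w1 + a[7] * w2;
    p[2] = o[2] + a[2] * w0 + a[5] * w1 + a[8] * w2;
  }
  inline double at(int i, int j, int k) const {
    return v[(size_t)i + (size_t)nx * ((size_t)j + (size_t)ny * k)];
  }
  // trilinear sample at continuous index; false when outside the support box
  inline bool tri(double x, double y, double z, double& out) const {
    if (x < 0.0 || y < 0.0 || z < 0.0 ||
        x > nx - 1.0 || y > ny - 1.0 || z > nz - 1.0) return false;
    int i0 = (int)std::floor(x), j0 = (int)std::floor(y), k0 = (int)std::floor(z);
    if (i0 > nx - 2) i0 = nx - 2; if (i0 < 0) i0 = 0;
    if (j0 > ny - 2) j0 = ny - 2; if (j0 < 0) j0 = 0;
    if (k0 > nz - 2) k0 = nz - 2; if (k0 < 0) k0 = 0;
    double fx = x - i0, fy = y - j0, fz = z - k0;
    double c00 = at(i0, j0, k0) * (1 - fx) + at(i0 + 1, j0, k0) * fx;
    double c10 = at(i0, j0 + 1, k0) * (1 - fx) + at(i0 + 1, j0 + 1, k0) * fx;
    double c01 = at(i0, j0, k0 + 1) * (1 - fx) + at(i0 + 1, j0, k0 + 1) * fx;
    double c11 = at(i0, j0 + 1, k0 + 1) * (1 - fx) + at(i0 + 1, j0 + 1, k0 + 1) * fx;
    double c0 = c00 * (1 - fy) + c10 * fy;
    double c1 = c01 * (1 - fy) + c11 * fy;
    out = c0 * (1 - fz) + c1 * fz;
    return true;
  }
  inline bool nearest(double x, double y, double z, double& out) const {
    if (x < -0.5 || y < -0.5 || z < -0.5 ||
        x >= nx - 0.5 || y >= ny - 0.5 || z >= nz - 0.5) return false;
    int i = (int)std::floor(x + 0.5), j = (int)std::floor(y + 0.5),
        k = (int)std::floor(z + 0.5);
    if (i < 0) i = 0; if (i > nx - 1) i = nx - 1;
    if (j < 0) j = 0; if (j > ny - 1) j = ny - 1;
    if (k < 0) k = 0; if (k > nz - 1) k = nz - 1;
    out = at(i, j, k);
    return true;
  }
};

static Grid make_grid(const NumericVector& values, const NumericVector& origin,
                      const NumericVector& spacing, const NumericVector& axes) {
  Grid g;
  IntegerVector d = values.attr("dim");
  if (d.size() != 3) stop("values must be a 3D array");
  g.v = REAL(values);
  g.nx = d[0]; g.ny = d[1]; g.nz = d[2];
  for (int i = 0; i < 3; ++i) { g.o[i] = origin[i]; g.s[i] = spacing[i]; }
  for (int i = 0; i < 9; ++i) g.a[i] = axes[i];
  return g;
}

// Siddon-style traversal: water-equivalent path length of segment p0->p1.
// Voxel i occupies the index interval [i-0.5, i+0.5]; the accumulated length
// of each intersected voxel is weighted by its value (relative density).
static double wepl_segment(const Grid& g, const double* p0, const double* p1) {
  double q0[3], q1[3];
  g.w2i(p0, q0);
  g.w2i(p1, q1);
  double d[3] = { q1[0] - q0[0], q1[1] - q0[1], q1[2] - q0[2] };
  double L = std::sqrt((p1[0] - p0[0]) * (p1[0] - p0[0]) +
                       (p1[1] - p0[1]) * (p1[1] - p0[1]) +
                       (p1[2] - p0[2]) * (p1[2] - p0[2]));
  if (L <= 0.0) return 0.0;
  const int n[3] = { g.nx, g.ny, g.nz };
  double tmin = 0.0, tmax = 1.0;
  for (int a = 0; a < 3; ++a) {
    if (std::fabs(d[a]) > 1e-12) {
      double t0 = (-0.5 - q0[a]) / d[a];
      double t1 = (n[a] - 0.5 - q0[a]) / d[a];
      if (t0 > t1) std::swap(t0, t1);
      if (t0 > tmin) tmin = t0;
      if (t1 < tmax) tmax = t1;
    } else if (q0[a] < -0.5 || q0[a] > n[a] - 0.5) {
      return 0.0;
    }
  }
  if (tmin >= tmax) return 0.0;
  double wepl = 0.0;
  double t = tmin;
  const double eps = 1e-10;
  while (t < tmax - eps) {
    double tn = tmax;
    for (int a = 0; a < 3; ++a) {
      if (std::fabs(d[a]) <= 1e-12) continue;
      double c = q0[a] + t * d[a];
      double b = (d[a] > 0) ? std::floor(c + 0.5) + 0.5
                            : std::ceil(c - 0.5) - 0.5;
      double tb = (b - q0[a]) / d[a];
      while (tb <= t + eps) {
        b += (d[a] > 0) ? 1.0 : -1.0;
        tb = (b - q0[a]) / d[a];
      }
      if (tb < tn) tn = tb;
    }
    double tm = 0.5 * (t + tn);
    int i = (int)std::floor(q0[0] + tm * d[0] + 0.5);
    int j = (int)std::floor(q0[1] + tm * d[1] + 0.5);
    int k = (int)std::floor(q0[2] + tm * d[2] + 0.5);
    if (i >= 0 && i < g.nx && j >= 0 && j < g.ny && k >= 0 && k < g.nz)
      wepl += g.at(i, j, k) * (tn - t) * L;
    t = tn;
  }
  return wepl;
}

// [[Rcpp::export]]
NumericVector cpp_wepl_batch(NumericVector values, NumericVector origin,
                             NumericVector spacing, NumericVector axes,
                             NumericMatrix src, NumericMatrix dst) {
  Grid g = make_grid(values, origin, spacing, axes);
  int nray = dst.nrow();
  bool one_src = (src.nrow() == 1);
  NumericVector out(nray);
  for (int r = 0; r < nray; ++r) {
    double p0[3], p1[3];
    int rs = one_src ? 0 : r;
    for (int a = 0; a < 3; ++a) { p0[a] = src(rs, a); p1[a] = dst(r, a); }
    out[r] = wepl_segment(g, p0, p1);
  }
  return out;
}

// Resample source volume on a target geometry through the affine map
// p_source = M %*% p_target + b (identity for plain grid-to-grid resampling).
// [[Rcpp::export]]
NumericVector cpp_resample_affine(NumericVector values, NumericVector origin,
                                  NumericVector spacing, NumericVector axes,
                                  IntegerVector tdim, NumericVector torigin,
                                  NumericVector tspacing, NumericVector taxes,
                                  NumericVector map, NumericVector off,
                                  bool nearest, double fill) {
  Grid g = make_grid(values, origin, spacing, axes);
  Grid t;
  t.v = nullptr;
  t.nx = tdim[0]; t.ny = tdim[1]; t.nz = tdim[2];
  for (int i = 0; i < 3; ++i) { t.o[i] = torigin[i]; t.s[i] = tspacing[i]; }
  for (int i = 0; i < 9; ++i) t.a[i] = taxes[i];
  size_t ntot = (size_t)t.nx * t.ny * t.nz;
  NumericVector out((R_xlen_t)ntot);
  size_t idx = 0;
  for (int k = 0; k < t.nz; ++k)
    for (int j = 0; j < t.ny; ++j)
      for (int i = 0; i < t.nx; ++i, ++idx) {
        double xi[3] = { (double)i, (double)j, (double)k };
        double p[3], ps[3], q[3];
        t.i2w(xi, p);
        ps[0] = map[0] * p[0] + map[3] * p[1] + map[6] * p[2] + off[0];
        ps[1] = map[1] * p[0] + map[4] * p[1] + map[7] * p[2] + off[1];
        ps[2] = map[2] * p[0] + map[5] * p[1] + map[8] * p[2] + off[2];
        g.w2i(ps, q);
        double val;
        bool ok = nearest ? g.nearest(q[0], q[1], q[2], val)
                          : g.tri(q[0], q[1], q[2], val);
        out[idx] = ok ? val : fill;
      }
  out.attr("dim") = tdim;
  return out;
}

// Raw dose of a set of divergent beams on the image grid itself: for each
// voxel, primary attenuation exp(-mu * WEPL(source -> voxel)) times a
// flat-field-with-Gaussian-penumbra lateral profile and an inverse-square
// factor normalised at the source-axis distance.
// beams: one row per beam = (sx,sy,sz, ix,iy,iz, aperture_mm, weight, sigma_mm)
// [[Rcpp::export]]
NumericVector cpp_plan_dose(NumericVector dens, NumericVector origin,
                            NumericVector spacing, NumericVector axes,
                            NumericMatrix beams, double mu_eff) {
  Grid g = make_grid(dens, origin, spacing, axes);
  size_t ntot = (size_t)g.nx * g.ny * g.nz;
  NumericVector out((R_xlen_t)ntot);
  int nb = beams.nrow();
  std::vector<double> sad(nb), ux(nb), uy(nb), uz(nb);
  for (int b = 0; b < nb; ++b) {
    double dx = beams(b, 3) - beams(b, 0);
    double dy = beams(b, 4) - beams(b, 1);
    double dz = beams(b, 5) - beams(b, 2);
    sad[b] = std::sqrt(dx * dx + dy * dy + dz * dz);
    ux[b] = dx / sad[b]; uy[b] = dy / sad[b]; uz[b] = dz / sad[b];
  }
  size_t idx = 0;
  for (int k = 0; k < g.nz; ++k) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < g.ny; ++j)
      for (int i = 0; i < g.nx; ++i, ++idx) {
        double xi[3] = { (double)i, (double)j, (double)k };
        double p[3];
        g.i2w(xi, p);
        double dose = 0.0;
        for (int b = 0; b < nb; ++b) {
          double src[3] = { beams(b, 0), beams(b, 1), beams(b, 2) };
          double vx = p[0] - src[0], vy = p[1] - src[1], vz = p[2] - src[2];
          double proj = vx * ux[b] + vy * uy[b] + vz * uz[b];
          if (proj <= 1.0) continue;  // behind or at the source
          double d2 = vx * vx + vy * vy + vz * vz;
          double r2 = d2 - proj * proj;
          double r = (r2 > 0.0) ? std::sqrt(r2) : 0.0;
          double field_r = beams(b, 6) * proj / sad[b];
          double lateral = 1.0;
          if (r > field_r) {
            double e = (r - field_r) / beams(b, 8);
            if (e > 6.0) continue;
            lateral = std::exp(-0.5 * e * e);
          }
          double w = wepl_segment(g, src, p);
          double invsq = (sad[b] * sad[b]) / d2;
          dose += beams(b, 7) * std::exp(-mu_eff * w) * lateral * invsq;
        }
        out[idx] = dose;
      }
  }
  out.attr("dim") = IntegerVector::create(g.nx, g.ny, g.nz);
  return out;
}

// Shared offset-lattice construction for both gamma routes: all integer
// multiples of step = interp_fraction * dta within |o| <= cap * dta.
struct Offset { double x, y, z, d2; };
static std::vector<Offset> gamma_offsets(double dta, double interp_fraction,
                                         double cap, bool sorted) {
  double step = interp_fraction * dta;
  double rad = cap * dta;
  int m = (int)std::floor(rad / step + 1e-9);
  std::vector<Offset> off;
  off.reserve((size_t)(2 * m + 1) * (2 * m + 1) * (2 * m + 1) / 2);
  for (int k = -m; k <= m; ++k)
    for (int j = -m; j <= m; ++j)
      for (int i = -m; i <= m; ++i) {
        double x = i * step, y = j * step, z = k * step;
        double d2 = x * x + y * y + z * z;
        if (d2 <= rad * rad + 1e-12) off.push_back({ x, y, z, d2 });
      }
  if (sorted)
    std::sort(off.begin(), off.end(),
              [](const Offset& a, const Offset& b) { return a.d2 < b.d2; });
  return off;
}

// 3D local gamma.  For every reference voxel at or above
// threshold_fraction * max(ref): minimise over the evaluated-dose sampling
// lattice sqrt(|o|^2/dta^2 + (De - Dr)^2 / (pct/100 * Dr)^2), clipped at cap.
// prune = true walks the lattice in increasing spatial distance and stops
// once the distance term alone can no longer improve the running minimum;
// prune = false is the exhaustive oracle.  Both share the same lattice and
// the same trilinear interpolator, so agreeing results are exact.
// [[Rcpp::export]]
List cpp_gamma(NumericVector rvals, NumericVector rorig, NumericVector rspac,
               NumericVector raxes, NumericVector evals, NumericVector eorig,
               NumericVector espac, NumericVector eaxes, double dose_percent,
               double dta_mm, double threshold_fraction, double cap,
               double interp_fraction, bool prune) {
  Grid ref = make_grid(rvals, rorig, rspac, raxes);
  Grid ev = make_grid(evals, eorig, espac, eaxes);
  size_t ntot = (size_t)ref.nx * ref.ny * ref.nz;
  double dmax = 0.0;
  for (size_t i = 0; i < ntot; ++i) if (ref.v[i] > dmax) dmax = ref.v[i];
  double thr = threshold_fraction * dmax;
  std::vector<Offset> off = gamma_offsets(dta_mm, interp_fraction, cap, prune);
  double dta2 = dta_mm * dta_mm;
  double cap2 = cap * cap;
  NumericVector out((R_xlen_t)ntot);
  size_t idx = 0, nincl = 0, npass = 0;
  for (int k = 0; k < ref.nz; ++k) {
    Rcpp::checkUserInterrupt();
    for (int j = 0; j < ref.ny; ++j)
      for (int i = 0; i < ref.nx; ++i, ++idx) {
        double dr = ref.v[idx];
        if (dr < thr || dmax <= 0.0) { out[idx] = NA_REAL; continue; }
        double xi[3] = { (double)i, (double)j, (double)k };
        double p[3];
        ref.i2w(xi, p);
        double denom = (dose_percent / 100.0) * dr;
        double best = R_PosInf;
        for (size_t n = 0; n < off.size(); ++n) {
          double sterm = off[n].d2 / dta2;
          if (prune && sterm >= best) break;
          double q[3], de;
          double pe[3] = { p[0] + off[n].x, p[1] + off[n].y, p[2] + off[n].z };
          ev.w2i(pe, q);
          if (!ev.tri(q[0], q[1], q[2], de)) continue;
          double dd = (de - dr) / denom;
          double g2 = sterm + dd * dd;
          if (g2 < best) best = g2;
        }
        double gam = (best <= cap2) ? std::sqrt(best) : cap;
        out[idx] = gam;
        ++nincl;
        if (gam <= 1.0) ++npass;
      }
  }
  out.attr("dim") = IntegerVector::create(ref.nx, ref.ny, ref.nz);
  double rate = (nincl > 0) ? 100.0 * (double)npass / (double)nincl : NA_REAL;
  return List::create(_["gamma"] = out, _["pass_rate"] = rate,
                      _["n_included"] = (double)nincl);
}

// 6-connected component labelling of a logical 3D array.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("mask must be a 3D array");
  int nx = d[0], ny = d[1], nz = d[2];
  size_t ntot = (size_t)nx * ny * nz;
  IntegerVector lab((R_xlen_t)ntot);
  int next = 0;
  std::vector<size_t> stack;
  for (size_t start = 0; start < ntot; ++start) {
    if (!mask[start] || lab[start] != 0) continue;
    ++next;
    stack.push_back(start);
    lab[start] = next;
    while (!stack.empty()) {
      size_t cur = stack.back();
      stack.pop_back();
      int i = cur % nx, j = (cur / nx) % ny, k = cur / ((size_t)nx * ny);
      const int di[6] = { -1, 1, 0, 0, 0, 0 };
      const int dj[6] = { 0, 0, -1, 1, 0, 0 };
      const int dk[6] = { 0, 0, 0, 0, -1, 1 };
      for (int m = 0; m < 6; ++m) {
        int ii = i + di[m], jj = j + dj[m], kk = k + dk[m];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        size_t nb = (size_t)ii + (size_t)nx * ((size_t)jj + (size_t)ny * kk);
        if (mask[nb] && lab[nb] == 0) { lab[nb] = next; stack.push_back(nb); }
      }
    }
  }
  lab.attr("dim") = d;
  return lab;
}
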