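// Voxel-level primitives for trabecular morphometry.
//
// All volumes are passed as logical vectors in R's column-major layout with
// dim = (n0, n1, n2); index (i0, i1, i2) maps to i0 + n0*(i1 + n1*i2).
// Axis 0 is the proximodistal slice axis throughout the package.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <cstdint>
using namespace Rcpp;

static inline R_xlen_t idx3(int i0, int i1, int i2, int n0, int n1) {
  return (R_xlen_t)i0 + (R_xlen_t)n0 * ((R_xlen_t)i1 + (R_xlen_t)n1 * (R_xlen_t)i2);
}

// ---------------------------------------------------------------------------
// Connected-component labelling (6- or 26-connectivity), iterative flood fill.
// Labels the TRUE voxels of `phase`; FALSE voxels get label 0.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector phase, IntegerVector dim,
                                   int connectivity) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (phase.size() != n) stop("dim does not match volume length");
  if (connectivity != 6 && connectivity != 26) stop("connectivity must be 6 or 26");

  std::vector<int> off0, off1, off2;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh != 1) continue;
        off0.push_back(a); off1.push_back(b); off2.push_back(c);
      }

  IntegerVector lab(n, 0);
  std::vector<R_xlen_t> stack;
  int next = 0;
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        R_xlen_t p = idx3(i0, i1, i2, n0, n1);
        if (!phase[p] || lab[p] != 0) continue;
        ++next;
        lab[p] = next;
        stack.clear();
        stack.push_back(p);
        while (!stack.empty()) {
          R_xlen_t q = stack.back(); stack.pop_back();
          int q0 = (int)(q % n0);
          int q1 = (int)((q / n0) % n1);
          int q2 = (int)(q / ((R_xlen_t)n0 * n1));
          for (size_t k = 0; k < off0.size(); ++k) {
            int r0 = q0 + off0[k], r1 = q1 + off1[k], r2 = q2 + off2[k];
            if (r0 < 0 || r0 >= n0 || r1 < 0 || r1 >= n1 || r2 < 0 || r2 >= n2)
              continue;
            R_xlen_t r = idx3(r0, r1, r2, n0, n1);
            if (phase[r] && lab[r] == 0) { lab[r] = next; stack.push_back(r); }
          }
        }
      }
  lab.attr("n_components") = next;
  return lab;
}

// ---------------------------------------------------------------------------
// Euler characteristic of the cubical complex spanned by foreground voxels:
// chi = V - E + F - C (vertices, edges, faces, cubes), treating the object
// as free-standing (no boundary correction).
// [[Rcpp::export]]
NumericVector cpp_euler_counts(LogicalVector fg, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (fg.size() != n) stop("dim does not match volume length");

  auto at = [&](int i0, int i1, int i2) -> bool {
    if (i0 < 0 || i0 >= n0 || i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2)
      return false;
    return fg[idx3(i0, i1, i2, n0, n1)];
  };

  double V = 0, E = 0, F = 0, C = 0;
  // cubes
  for (R_xlen_t p = 0; p < n; ++p) if (fg[p]) C += 1;
  // vertices: lattice point (i0,i1,i2) with adjacent voxels (i0-1..i0, ...)
  for (int i2 = 0; i2 <= n2; ++i2)
    for (int i1 = 0; i1 <= n1; ++i1)
      for (int i0 = 0; i0 <= n0; ++i0) {
        bool any = false;
        for (int a = i0 - 1; a <= i0 && !any; ++a)
          for (int b = i1 - 1; b <= i1 && !any; ++b)
            for (int c = i2 - 1; c <= i2 && !any; ++c)
              if (at(a, b, c)) any = true;
        if (any) V += 1;
      }
  // edges along axis 0: span (i0, i0+1) at lattice line (i1, i2)
  for (int i2 = 0; i2 <= n2; ++i2)
    for (int i1 = 0; i1 <= n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        bool any = at(i0, i1 - 1, i2 - 1) || at(i0, i1, i2 - 1) ||
                   at(i0, i1 - 1, i2) || at(i0, i1, i2);
        if (any) E += 1;
      }
  // edges along axis 1
  for (int i2 = 0; i2 <= n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 <= n0; ++i0) {
        bool any = at(i0 - 1, i1, i2 - 1) || at(i0, i1, i2 - 1) ||
                   at(i0 - 1, i1, i2) || at(i0, i1, i2);
        if (any) E += 1;
      }
  // edges along axis 2
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 <= n1; ++i1)
      for (int i0 = 0; i0 <= n0; ++i0) {
        bool any = at(i0 - 1, i1 - 1, i2) || (at(i0, i1 - 1, i2)) ||
                   at(i0 - 1, i1, i2) || at(i0, i1, i2);
        if (any) E += 1;
      }
  // faces normal to axis 0: between voxels (i0-1,*) and (i0,*)
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 <= n0; ++i0)
        if (at(i0 - 1, i1, i2) || at(i0, i1, i2)) F += 1;
  // faces normal to axis 1
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 <= n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0)
        if (at(i0, i1 - 1, i2) || at(i0, i1, i2)) F += 1;
  // faces normal to axis 2
  for (int i2 = 0; i2 <= n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0)
        if (at(i0, i1, i2 - 1) || at(i0, i1, i2)) F += 1;

  return NumericVector::create(_["V"] = V, _["E"] = E, _["F"] = F, _["C"] = C,
                               _["chi"] = V - E + F - C);
}

// ---------------------------------------------------------------------------
// Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
// separable 1-D lower envelopes along each axis.  Distance of each TRUE
// voxel of `phase` to the nearest FALSE voxel centre, in voxel units.
static void dt1d(std::vector<double>& f, std::vector<double>& d,
                 std::vector<int>& v, std::vector<double>& z, int n) {
  int k = 0;
  v[0] = 0;
  z[0] = -HUGE_VAL;
  z[1] = HUGE_VAL;
  for (int q = 1; q < n; ++q) {
    double s;
    while (true) {
      s = ((f[q] + q * (double)q) - (f[v[k]] + v[k] * (double)v[k])) /
          (2.0 * q - 2.0 * v[k]);
      if (s <= z[k]) { --k; } else break;
    }
    ++k;
    v[k] = q;
    z[k] = s;
    z[k + 1] = HUGE_VAL;
  }
  k = 0;
  for (int q = 0; q < n; ++q) {
    while (z[k + 1] < q) ++k;
    double dq = q - (double)v[k];
    d[q] = dq * dq + f[v[k]];
  }
}

// [[Rcpp::export]]
NumericVector cpp_edt_sq(LogicalVector phase, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (phase.size() != n) stop("dim does not match volume length");
  std::vector<double> d2(n);
  const double INF = 1e20;
  for (R_xlen_t p = 0; p < n; ++p) d2[p] = phase[p] ? INF : 0.0;

  int nmax = std::max(n0, std::max(n1, n2));
  std::vector<double> f(nmax), d(nmax), z(nmax + 1);
  std::vector<int> v(nmax);

  // axis 0
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1) {
      for (int i0 = 0; i0 < n0; ++i0) f[i0] = d2[idx3(i0, i1, i2, n0, n1)];
      dt1d(f, d, v, z, n0);
      for (int i0 = 0; i0 < n0; ++i0) d2[idx3(i0, i1, i2, n0, n1)] = d[i0];
    }
  // axis 1
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i0 = 0; i0 < n0; ++i0) {
      for (int i1 = 0; i1 < n1; ++i1) f[i1] = d2[idx3(i0, i1, i2, n0, n1)];
      dt1d(f, d, v, z, n1);
      for (int i1 = 0; i1 < n1; ++i1) d2[idx3(i0, i1, i2, n0, n1)] = d[i1];
    }
  // axis 2
  for (int i1 = 0; i1 < n1; ++i1)
    for (int i0 = 0; i0 < n0; ++i0) {
      for (int i2 = 0; i2 < n2; ++i2) f[i2] = d2[idx3(i0, i1, i2, n0, n1)];
      dt1d(f, d, v, z, n2);
      for (int i2 = 0; i2 < n2; ++i2) d2[idx3(i0, i1, i2, n0, n1)] = d[i2];
    }

  return NumericVector(d2.begin(), d2.end());
}

// ---------------------------------------------------------------------------
// Model-independent local thickness (Hildebrand & Ruegsegger): per-voxel
// diameter of the largest inscribed sphere containing the voxel.  Spheres
// are painted from candidate centres; a centre is skipped when one of its
// 26 neighbours carries a sphere that fully contains its own (dominance
// pruning, which leaves the distance-ridge generators intact).
// [[Rcpp::export]]
NumericVector cpp_local_thickness(NumericVector d2, IntegerVector dim) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (d2.size() != n) stop("dim does not match volume length");

  std::vector<double> r(n);
  for (R_xlen_t p = 0; p < n; ++p) r[p] = d2[p] > 0 ? std::sqrt(d2[p]) : 0.0;

  NumericVector th(n, 0.0);
  for (int i2 = 0; i2 < n2; ++i2)
    for (int i1 = 0; i1 < n1; ++i1)
      for (int i0 = 0; i0 < n0; ++i0) {
        R_xlen_t p = idx3(i0, i1, i2, n0, n1);
        double rp = r[p];
        if (rp <= 0) continue;
        // dominance pruning against 26-neighbourhood
        bool dominated = false;
        for (int a = -1; a <= 1 && !dominated; ++a)
          for (int b = -1; b <= 1 && !dominated; ++b)
            for (int c = -1; c <= 1 && !dominated; ++c) {
              if (a == 0 && b == 0 && c == 0) continue;
              int q0 = i0 + a, q1 = i1 + b, q2 = i2 + c;
              if (q0 < 0 || q0 >= n0 || q1 < 0 || q1 >= n1 || q2 < 0 || q2 >= n2)
                continue;
              double rq = r[idx3(q0, q1, q2, n0, n1)];
              double dist = std::sqrt((double)(a * a + b * b + c * c));
              if (rq >= rp + dist - 1e-9) dominated = true;
            }
        if (dominated) continue;
        int R = (int)std::floor(rp);
        double diam = 2.0 * rp;
        for (int a = -R; a <= R; ++a) {
          int q0 = i0 + a;
          if (q0 < 0 || q0 >= n0) continue;
          for (int b = -R; b <= R; ++b) {
            int q1 = i1 + b;
            if (q1 < 0 || q1 >= n1) continue;
            for (int c = -R; c <= R; ++c) {
              int q2 = i2 + c;
              if (q2 < 0 || q2 >= n2) continue;
              if (a * a + b * b + c * c > rp * rp) continue;
              R_xlen_t q = idx3(q0, q1, q2, n0, n1);
              if (r[q] > 0 && th[q] < diam) th[q] = diam;
            }
          }
        }
      }
  return th;
}

// ---------------------------------------------------------------------------
// Directed parallel-line scan used by both the MIL fabric tensor and the
// Cauchy-Crofton surface estimator.  For each direction (rows of `dirs`,
// unit vectors in index space) a grid of parallel lines with spacing
// `line_spacing` (voxels) and per-direction random offsets `offs` (n x 2,
// each in [0,1)) is marched with step `step`; samples take the value of the
// nearest voxel.  Returns per-direction totals: in-volume line length,
// phase-boundary crossings, and bone-phase length (all in voxel units).
// When `trilinear` is true, samples take the trilinearly interpolated value
// of the indicator (zero outside the volume) and the bone phase is val>=0.5;
// this measures the smoothed 0.5-isosurface and removes the staircase bias
// of the digitised boundary (used for the Crofton surface estimate).
// [[Rcpp::export]]
NumericMatrix cpp_line_scan(NumericVector fg, IntegerVector dim,
                            NumericMatrix dirs, double line_spacing,
                            double step, NumericMatrix offs,
                            bool trilinear = false) {
  const int n0 = dim[0], n1 = dim[1], n2 = dim[2];
  const R_xlen_t n = (R_xlen_t)n0 * n1 * n2;
  if (fg.size() != n) stop("dim does not match volume length");
  const int nd = dirs.nrow();
  if (offs.nrow() != nd || offs.ncol() != 2) stop("offs must be n_directions x 2");
  if (line_spacing <= 0 || step <= 0) stop("line_spacing and step must be > 0");

  NumericMatrix out(nd, 3);
  colnames(out) = CharacterVector::create("length", "crossings", "bone");

  const double lo0 = -0.5, hi0 = n0 - 0.5;
  const double lo1 = -0.5, hi1 = n1 - 0.5;
  const double lo2 = -0.5, hi2 = n2 - 0.5;
  const double c0 = (n0 - 1) / 2.0, c1 = (n1 - 1) / 2.0, c2 = (n2 - 1) / 2.0;

  for (int k = 0; k < nd; ++k) {
    double d0 = dirs(k, 0), d1 = dirs(k, 1), d2v = dirs(k, 2);
    // orthonormal basis perpendicular to d
    double a0, a1, a2;
    if (std::fabs(d0) < 0.9) { a0 = 1; a1 = 0; a2 = 0; }
    else { a0 = 0; a1 = 1; a2 = 0; }
    // u = normalize(a - (a.d) d)
    double ad = a0 * d0 + a1 * d1 + a2 * d2v;
    double u0 = a0 - ad * d0, u1 = a1 - ad * d1, u2 = a2 - ad * d2v;
    double un = std::sqrt(u0 * u0 + u1 * u1 + u2 * u2);
    u0 /= un; u1 /= un; u2 /= un;
    // v = d x u
    double v0 = d1 * u2 - d2v * u1;
    double v1 = d2v * u0 - d0 * u2;
    double v2 = d0 * u1 - d1 * u0;

    // projection range of the box corners onto u and v (relative to centre)
    double umin = HUGE_VAL, umax = -HUGE_VAL, vmin = HUGE_VAL, vmax = -HUGE_VAL;
    for (int ci = 0; ci < 8; ++ci) {
      double p0 = (ci & 1) ? hi0 : lo0;
      double p1 = (ci & 2) ? hi1 : lo1;
      double p2 = (ci & 4) ? hi2 : lo2;
      double pu = (p0 - c0) * u0 + (p1 - c1) * u1 + (p2 - c2) * u2;
      double pv = (p0 - c0) * v0 + (p1 - c1) * v1 + (p2 - c2) * v2;
      if (pu < umin) umin = pu;
      if (pu > umax) umax = pu;
      if (pv < vmin) vmin = pv;
      if (pv > vmax) vmax = pv;
    }

    double totlen = 0, totcross = 0, totbone = 0;
    for (double au = umin + offs(k, 0) * line_spacing; au <= umax;
         au += line_spacing) {
      for (double av = vmin + offs(k, 1) * line_spacing; av <= vmax;
           av += line_spacing) {
        double o0 = c0 + au * u0 + av * v0;
        double o1 = c1 + au * u1 + av * v1;
        double o2 = c2 + au * u2 + av * v2;
        // slab clipping of line o + t d against the box
        double t0 = -HUGE_VAL, t1 = HUGE_VAL;
        bool miss = false;
        double o[3] = {o0, o1, o2};
        double dd[3] = {d0, d1, d2v};
        double lo[3] = {lo0, lo1, lo2};
        double hi[3] = {hi0, hi1, hi2};
        for (int ax = 0; ax < 3; ++ax) {
          if (std::fabs(dd[ax]) < 1e-12) {
            if (o[ax] < lo[ax] || o[ax] > hi[ax]) { miss = true; break; }
          } else {
            double ta = (lo[ax] - o[ax]) / dd[ax];
            double tb = (hi[ax] - o[ax]) / dd[ax];
            if (ta > tb) { double tmp = ta; ta = tb; tb = tmp; }
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
          }
        }
        if (miss || t1 <= t0) continue;

        int prev = -1;  // -1 before the first in-volume sample
        long nsamp = 0, nbone = 0, ncross = 0;
        for (double t = t0 + step * 0.5; t < t1; t += step) {
          double p0 = o0 + t * d0, p1 = o1 + t * d1, p2 = o2 + t * d2v;
          int cur;
          if (!trilinear) {
            int i0 = (int)std::lround(p0);
            int i1 = (int)std::lround(p1);
            int i2 = (int)std::lround(p2);
            if (i0 < 0 || i0 >= n0 || i1 < 0 || i1 >= n1 || i2 < 0 || i2 >= n2)
              continue;
            cur = fg[idx3(i0, i1, i2, n0, n1)] >= 0.5 ? 1 : 0;
          } else {
            int f0 = (int)std::floor(p0), f1 = (int)std::floor(p1),
                f2 = (int)std::floor(p2);
            double w0 = p0 - f0, w1 = p1 - f1, w2 = p2 - f2;
            double val = 0.0;
            for (int a = 0; a <= 1; ++a)
              for (int b = 0; b <= 1; ++b)
                for (int c = 0; c <= 1; ++c) {
                  int i0 = f0 + a, i1 = f1 + b, i2 = f2 + c;
                  if (i0 < 0 || i0 >= n0 || i1 < 0 || i1 >= n1 ||
                      i2 < 0 || i2 >= n2)
                    continue;  // outside = 0
                  val += fg[idx3(i0, i1, i2, n0, n1)] *
                         (a ? w0 : 1 - w0) * (b ? w1 : 1 - w1) *
                         (c ? w2 : 1 - w2);
                }
            cur = val >= 0.5 ? 1 : 0;
          }
          ++nsamp;
          if (cur) ++nbone;
          if (prev >= 0 && cur != prev) ++ncross;
          prev = cur;
        }
        totlen += nsamp * step;
        totbone += nbone * step;
        totcross += ncross;
      }
    }
    out(k, 0) = totlen;
    out(k, 1) = totcross;
    out(k, 2) = totbone;
  }
  return out;
}
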