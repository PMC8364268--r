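#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Shared kernels for the gamma-index distance-to-agreement search and rigid
// resampling. Arrays follow R's column-major layout with dims (slice, row,
// column); all physical quantities are in mm, voxel coordinates 0-based.

namespace {

struct Candidate {
  double dist2;          // squared physical offset, mm^2
  int i0, j0, k0;        // integer part of the voxel-space offset
  double w[8];           // trilinear corner weights (000..111, i fastest)
  bool fi, fj, fk;       // whether the fractional part along each axis is nonzero
};

inline long lin(int i, int j, int k, int n1, int n2) {
  return (long)i + (long)n1 * ((long)j + (long)n2 * (long)k);
}

// Build the candidate offset list for the minimisation, sorted by distance so
// the per-voxel scan can stop once the distance term alone exceeds the
// running minimum. step <= 0 selects the exact integer-grid mode.
std::vector<Candidate> build_candidates(const NumericVector& spacing,
                                        double radius, double step) {
  std::vector<Candidate> cands;
  const double r2 = radius * radius;
  if (step <= 0.0) {
    int m1 = (int)std::floor(radius / spacing[0]);
    int m2 = (int)std::floor(radius / spacing[1]);
    int m3 = (int)std::floor(radius / spacing[2]);
    for (int a = -m1; a <= m1; ++a)
      for (int b = -m2; b <= m2; ++b)
        for (int c = -m3; c <= m3; ++c) {
          double d2 = a * spacing[0] * a * spacing[0] +
                      b * spacing[1] * b * spacing[1] +
                      c * spacing[2] * c * spacing[2];
          if (d2 > r2 + 1e-12) continue;
          Candidate cd;
          cd.dist2 = d2;
          cd.i0 = a; cd.j0 = b; cd.k0 = c;
          for (int q = 0; q < 8; ++q) cd.w[q] = 0.0;
          cd.w[0] = 1.0;
          cd.fi = cd.fj = cd.fk = false;
          cands.push_back(cd);
        }
  } else {
    int m = (int)std::floor(radius / step);
    for (int a = -m; a <= m; ++a)
      for (int b = -m; b <= m; ++b)
        for (int c = -m; c <= m; ++c) {
          double oz = a * step, oy = b * step, ox = c * step;
          double d2 = oz * oz + oy * oy + ox * ox;
          if (d2 > r2 + 1e-12) continue;
          // offset in voxel units along each array axis
          double vz = oz / spacing[0], vy = oy / spacing[1], vx = ox / spacing[2];
          Candidate cd;
          cd.dist2 = d2;
          double bi = std::floor(vz), bj = std::floor(vy), bk = std::floor(vx);
          double ti = vz - bi, tj = vy - bj, tk = vx - bk;
          // snap near-integer offsets so axis-aligned candidates stay exact
          if (ti < 1e-9) ti = 0.0; else if (ti > 1 - 1e-9) { ti = 0.0; bi += 1; }
          if (tj < 1e-9) tj = 0.0; else if (tj > 1 - 1e-9) { tj = 0.0; bj += 1; }
          if (tk < 1e-9) tk = 0.0; else if (tk > 1 - 1e-9) { tk = 0.0; bk += 1; }
          cd.i0 = (int)bi; cd.j0 = (int)bj; cd.k0 = (int)bk;
          cd.fi = ti > 0.0; cd.fj = tj > 0.0; cd.fk = tk > 0.0;
          cd.w[0] = (1 - ti) * (1 - tj) * (1 - tk);
          cd.w[1] = ti * (1 - tj) * (1 - tk);
          cd.w[2] = (1 - ti) * tj * (1 - tk);
          cd.w[3] = ti * tj * (1 - tk);
          cd.w[4] = (1 - ti) * (1 - tj) * tk;
          cd.w[5] = ti * (1 - tj) * tk;
          cd.w[6] = (1 - ti) * tj * tk;
          cd.w[7] = ti * tj * tk;
          cands.push_back(cd);
        }
  }
  std::sort(cands.begin(), cands.end(),
            [](const Candidate& x, const Candidate& y) { return x.dist2 < y.dist2; });
  return cands;
}

}  // namespace

// [[Rcpp::export(name = ".gamma_kernel")]]
NumericVector gamma_kernel(NumericVector ref, NumericVector ev, LogicalVector mask,
                           IntegerVector dims, NumericVector spacing,
                           double dta, double delta, double radius, double step) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const double dta2 = dta * dta, inv_delta = 1.0 / delta;
  std::vector<Candidate> cands = build_candidates(spacing, radius, step);
  const double* pr = REAL(ref);
  const double* pe = REAL(ev);
  NumericVector out(ref.size(), NA_REAL);
  double* po = REAL(out);

  // precomputed corner linear offsets + interior bounds for the fast path
  const size_t nc = cands.size();
  std::vector<long> coff(nc * 8);
  std::vector<double> cdist(nc), cw(nc * 8);
  int lo1 = 0, hi1 = 0, lo2 = 0, hi2 = 0, lo3 = 0, hi3 = 0;
  for (size_t c = 0; c < nc; ++c) {
    const Candidate& cd = cands[c];
    int i1o = cd.fi ? cd.i0 + 1 : cd.i0;
    int j1o = cd.fj ? cd.j0 + 1 : cd.j0;
    int k1o = cd.fk ? cd.k0 + 1 : cd.k0;
    lo1 = std::min(lo1, cd.i0); hi1 = std::max(hi1, i1o);
    lo2 = std::min(lo2, cd.j0); hi2 = std::max(hi2, j1o);
    lo3 = std::min(lo3, cd.k0); hi3 = std::max(hi3, k1o);
    long base000 = lin(cd.i0, cd.j0, cd.k0, n1, n2);
    long di = i1o - cd.i0;
    long dj = (long)(j1o - cd.j0) * n1;
    long dk = (long)(k1o - cd.k0) * n1 * n2;
    coff[c * 8 + 0] = base000;
    coff[c * 8 + 1] = base000 + di;
    coff[c * 8 + 2] = base000 + dj;
    coff[c * 8 + 3] = base000 + di + dj;
    coff[c * 8 + 4] = base000 + dk;
    coff[c * 8 + 5] = base000 + di + dk;
    coff[c * 8 + 6] = base000 + dj + dk;
    coff[c * 8 + 7] = base000 + di + dj + dk;
    cdist[c] = cd.dist2 / dta2;
    for (int q = 0; q < 8; ++q) cw[c * 8 + q] = cd.w[q];
  }

  for (int k = 0; k < n3; ++k)
    for (int j = 0; j < n2; ++j)
      for (int i = 0; i < n1; ++i) {
        long idx = lin(i, j, k, n1, n2);
        if (mask[idx] == 0 || mask[idx] == NA_LOGICAL) continue;
        double rv = pr[idx];
        if (!std::isfinite(rv)) continue;  // excluded voxel, stays NA
        double best = R_PosInf;
        bool interior = i + lo1 >= 0 && i + hi1 <= n1 - 1 &&
                        j + lo2 >= 0 && j + hi2 <= n2 - 1 &&
                        k + lo3 >= 0 && k + hi3 <= n3 - 1;
        if (interior) {
          for (size_t c = 0; c < nc; ++c) {
            double dterm = cdist[c];
            if (dterm >= best) break;
            const long* o = &coff[c * 8];
            const double* w = &cw[c * 8];
            double v = w[0] * pe[idx + o[0]] + w[1] * pe[idx + o[1]] +
                       w[2] * pe[idx + o[2]] + w[3] * pe[idx + o[3]] +
                       w[4] * pe[idx + o[4]] + w[5] * pe[idx + o[5]] +
                       w[6] * pe[idx + o[6]] + w[7] * pe[idx + o[7]];
            if (!std::isfinite(v)) continue;
            double dv = (v - rv) * inv_delta;
            double g2 = dterm + dv * dv;
            if (g2 < best) best = g2;
          }
          po[idx] = std::isfinite(best) ? std::sqrt(best) : NA_REAL;
          continue;
        }
        for (const Candidate& cd : cands) {
          double dterm = cd.dist2 / dta2;
          if (dterm >= best) break;  // sorted by distance: no better candidate left
          int i0 = i + cd.i0, j0 = j + cd.j0, k0 = k + cd.k0;
          int i1 = cd.fi ? i0 + 1 : i0;
          int j1 = cd.fj ? j0 + 1 : j0;
          int k1 = cd.fk ? k0 + 1 : k0;
          if (i0 < 0 || j0 < 0 || k0 < 0 || i1 > n1 - 1 || j1 > n2 - 1 || k1 > n3 - 1)
            continue;
          double v;
          if (!cd.fi && !cd.fj && !cd.fk) {
            v = pe[lin(i0, j0, k0, n1, n2)];
          } else {
            v = cd.w[0] * pe[lin(i0, j0, k0, n1, n2)] +
                cd.w[1] * pe[lin(i1, j0, k0, n1, n2)] +
                cd.w[2] * pe[lin(i0, j1, k0, n1, n2)] +
                cd.w[3] * pe[lin(i1, j1, k0, n1, n2)] +
                cd.w[4] * pe[lin(i0, j0, k1, n1, n2)] +
                cd.w[5] * pe[lin(i1, j0, k1, n1, n2)] +
                cd.w[6] * pe[lin(i0, j1, k1, n1, n2)] +
                cd.w[7] * pe[lin(i1, j1, k1, n1, n2)];
          }
          if (!std::isfinite(v)) continue;
          double dv = (v - rv) * inv_delta;
          double g2 = dterm + dv * dv;
          if (g2 < best) best = g2;
        }
        po[idx] = std::isfinite(best) ? std::sqrt(best) : NA_REAL;
      }
  return out;
}

// [[Rcpp::export(name = ".resample_kernel")]]
NumericVector resample_kernel(NumericVector mov, IntegerVector mdims,
                              NumericVector mspacing, NumericVector morigin,
                              IntegerVector rdims, NumericVector rspacing,
                              NumericVector rorigin, NumericMatrix rot,
                              NumericVector trans, double fill, int nearest) {
  const int m1 = mdims[0], m2 = mdims[1], m3 = mdims[2];
  const int r1 = rdims[0], r2 = rdims[1], r3 = rdims[2];
  NumericVector out((R_xlen_t)r1 * r2 * r3);
  double* po = REAL(out);
  const double* pm = REAL(mov);
  const double a11 = rot(0, 0), a12 = rot(0, 1), a13 = rot(0, 2);
  const double a21 = rot(1, 0), a22 = rot(1, 1), a23 = rot(1, 2);
  const double a31 = rot(2, 0), a32 = rot(2, 1), a33 = rot(2, 2);

  for (int k = 0; k < r3; ++k)
    for (int j = 0; j < r2; ++j)
      for (int i = 0; i < r1; ++i) {
        double p1 = rorigin[0] + i * rspacing[0];
        double p2 = rorigin[1] + j * rspacing[1];
        double p3 = rorigin[2] + k * rspacing[2];
        // physical point in the moving frame
        double q1 = a11 * p1 + a12 * p2 + a13 * p3 + trans[0];
        double q2 = a21 * p1 + a22 * p2 + a23 * p3 + trans[1];
        double q3 = a31 * p1 + a32 * p2 + a33 * p3 + trans[2];
        double f1 = (q1 - morigin[0]) / mspacing[0];
        double f2 = (q2 - morigin[1]) / mspacing[1];
        double f3 = (q3 - morigin[2]) / mspacing[2];
        // snap to the lattice so coincident grids reproduce exactly
        if (std::fabs(f1 - std::round(f1)) < 1e-9) f1 = std::round(f1);
        if (std::fabs(f2 - std::round(f2)) < 1e-9) f2 = std::round(f2);
        if (std::fabs(f3 - std::round(f3)) < 1e-9) f3 = std::round(f3);
        long oidx = lin(i, j, k, r1, r2);
        if (f1 < 0 || f2 < 0 || f3 < 0 || f1 > m1 - 1 || f2 > m2 - 1 || f3 > m3 - 1) {
          po[oidx] = fill;
          continue;
        }
        if (nearest) {
          int i0 = (int)std::round(f1), j0 = (int)std::round(f2), k0 = (int)std::round(f3);
          po[oidx] = pm[lin(i0, j0, k0, m1, m2)];
          continue;
        }
        int i0 = (int)std::floor(f1), j0 = (int)std::floor(f2), k0 = (int)std::floor(f3);
        double ti = f1 - i0, tj = f2 - j0, tk = f3 - k0;
        int i1 = ti > 0 ? i0 + 1 : i0;
        int j1 = tj > 0 ? j0 + 1 : j0;
        int k1 = tk > 0 ? k0 + 1 : k0;
        double v =
            (1 - ti) * (1 - tj) * (1 - tk) * pm[lin(i0, j0, k0, m1, m2)] +
            ti * (1 - tj) * (1 - tk) * pm[lin(i1, j0, k0, m1, m2)] +
            (1 - ti) * tj * (1 - tk) * pm[lin(i0, j1, k0, m1, m2)] +
            ti * tj * (1 - tk) * pm[lin(i1, j1, k0, m1, m2)] +
            (1 - ti) * (1 - tj) * tk * pm[lin(i0, j0, k1, m1, m2)] +
            ti * (1 - tj) * tk * pm[lin(i1, j0, k1, m1, m2)] +
            (1 - ti) * tj * tk * pm[lin(i0, j1, k1, m1, m2)] +
            ti * tj * tk * pm[lin(i1, j1, k1, m1, m2)];
        po[oidx] = v;
      }
  return out;
}
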