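#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Trilinear sample of a 3D grid at continuous 0-based index (gx, gy, gz).
// Outside the voxel-center hull -> 0 (phantoms keep a margin of background).
static inline double sample3(const double *a, int nx, int ny, int nz,
                             double gx, double gy, double gz) {
  if (gx < 0.0 || gy < 0.0 || gz < 0.0 ||
      gx > nx - 1.0 || gy > ny - 1.0 || gz > nz - 1.0)
    return 0.0;
  int i0 = (int)gx; if (i0 > nx - 2) i0 = nx - 2;
  int j0 = (int)gy; if (j0 > ny - 2) j0 = ny - 2;
  int k0 = (int)gz; if (k0 > nz - 2) k0 = nz - 2;
  double fx = gx - i0, fy = gy - j0, fz = gz - k0;
  const R_xlen_t nxy = (R_xlen_t)nx * ny;
  const double *p = a + i0 + (R_xlen_t)j0 * nx + (R_xlen_t)k0 * nxy;
  double c00 = p[0] * (1 - fx) + p[1] * fx;
  double c10 = p[nx] * (1 - fx) + p[nx + 1] * fx;
  double c01 = p[nxy] * (1 - fx) + p[nxy + 1] * fx;
  double c11 = p[nxy + nx] * (1 - fx) + p[nxy + nx + 1] * fx;
  return (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
         (c01 * (1 - fy) + c11 * fy) * fz;
}

// Divergent-beam line integrals: one DRR per row of src/d0/eu/ev.
// Fixed-step sampling (step <= step_req), trilinear interpolation,
// integral scaled by the actual step length in mm.
// [[Rcpp::export]]
NumericVector cpp_drr(NumericVector vol, IntegerVector dims,
                      NumericVector voxel, NumericVector origin,
                      NumericMatrix src, NumericMatrix d0,
                      NumericMatrix eu, NumericMatrix ev,
                      int nu, int nv, double pix, double sdd,
                      double step_req) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int na = src.nrow();
  const double *a = REAL(vol);
  NumericVector out((R_xlen_t)nu * nv * na);
  double lo[3], hi[3];
  for (int ax = 0; ax < 3; ++ax) {
    lo[ax] = origin[ax] - voxel[ax] / 2.0;
    hi[ax] = origin[ax] + (dims[ax] - 1) * voxel[ax] + voxel[ax] / 2.0;
  }
  for (int n = 0; n < na; ++n) {
    double S[3], E[3], V[3], C[3];
    for (int ax = 0; ax < 3; ++ax) {
      S[ax] = src(n, ax);
      E[ax] = eu(n, ax);
      V[ax] = ev(n, ax);
      C[ax] = S[ax] + sdd * d0(n, ax);
    }
    double *img = REAL(out) + (R_xlen_t)n * nu * nv;
    for (int jv = 0; jv < nv; ++jv) {
      double v = (jv + 1 - (nv + 1) / 2.0) * pix;
      for (int iu = 0; iu < nu; ++iu) {
        double u = (iu + 1 - (nu + 1) / 2.0) * pix;
        double D[3], dn = 0.0;
        for (int ax = 0; ax < 3; ++ax) {
          D[ax] = C[ax] + u * E[ax] + v * V[ax] - S[ax];
          dn += D[ax] * D[ax];
        }
        dn = std::sqrt(dn);
        double t0 = -1e300, t1 = 1e300;
        bool miss = false;
        for (int ax = 0; ax < 3; ++ax) {
          D[ax] /= dn;
          if (D[ax] == 0.0) {
            if (S[ax] < lo[ax] || S[ax] > hi[ax]) { miss = true; break; }
          } else {
            double ta = (lo[ax] - S[ax]) / D[ax];
            double tb = (hi[ax] - S[ax]) / D[ax];
            if (ta > tb) std::swap(ta, tb);
            if (ta > t0) t0 = ta;
            if (tb < t1) t1 = tb;
          }
        }
        if (miss || t1 <= t0) continue;
        int ns = (int)std::ceil((t1 - t0) / step_req);
        double dt = (t1 - t0) / ns;
        double s = 0.0;
        for (int k = 0; k < ns; ++k) {
          double t = t0 + (k + 0.5) * dt;
          s += sample3(a, nx, ny, nz,
                       (S[0] + t * D[0] - origin[0]) / voxel[0],
                       (S[1] + t * D[1] - origin[1]) / voxel[1],
                       (S[2] + t * D[2] - origin[2]) / voxel[2]);
        }
        img[(R_xlen_t)jv * nu + iu] = s * dt;
      }
    }
  }
  return out;
}

// FDK-weighted back-projection of filtered projections onto a voxel grid in
// patient axes. For each voxel and view: project onto the detector along the
// divergent beam, sample bilinearly, weight by SAD^2/U^2 (U = distance from
// source along the central-ray direction) and by the angular step (radians).
// [[Rcpp::export]]
NumericVector cpp_backproject(NumericVector filt, int nu, int nv,
                              NumericMatrix src, NumericMatrix d0,
                              NumericMatrix eu, NumericMatrix ev,
                              double sad, double sdd, double pix,
                              double dbeta,
                              IntegerVector gdims, NumericVector gvox,
                              NumericVector gorig) {
  const int np = src.nrow();
  const int nx = gdims[0], ny = gdims[1], nz = gdims[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  double *o = REAL(out);
  const double *f = REAL(filt);
  const double sad2 = sad * sad;
  const double u_half = (nu + 1) / 2.0, v_half = (nv + 1) / 2.0;
  for (int n = 0; n < np; ++n) {
    const double *fp = f + (R_xlen_t)n * nu * nv;
    double S0 = src(n, 0), S1 = src(n, 1), S2 = src(n, 2);
    double A0 = d0(n, 0), A1 = d0(n, 1), A2 = d0(n, 2);
    double E0 = eu(n, 0), E1 = eu(n, 1), E2 = eu(n, 2);
    double V0 = ev(n, 0), V1 = ev(n, 1), V2 = ev(n, 2);
    R_xlen_t idx = 0;
    for (int k = 0; k < nz; ++k) {
      double z = gorig[2] + k * gvox[2];
      for (int j = 0; j < ny; ++j) {
        double y = gorig[1] + j * gvox[1];
        for (int i = 0; i < nx; ++i, ++idx) {
          double x = gorig[0] + i * gvox[0];
          double w0 = x - S0, w1 = y - S1, w2 = z - S2;
          double U = w0 * A0 + w1 * A1 + w2 * A2;
          if (U <= 1e-6) continue;
          double m = sdd / U;
          double pu = (w0 * E0 + w1 * E1 + w2 * E2) * m / pix + u_half - 1.0;
          double pv = (w0 * V0 + w1 * V1 + w2 * V2) * m / pix + v_half - 1.0;
          if (pu < 0.0 || pv < 0.0 || pu > nu - 1.0 || pv > nv - 1.0) continue;
          int iu = (int)pu; if (iu > nu - 2) iu = nu - 2;
          int iv = (int)pv; if (iv > nv - 2) iv = nv - 2;
          double fu = pu - iu, fv = pv - iv;
          const double *q = fp + (R_xlen_t)iv * nu + iu;
          double val = (q[0] * (1 - fu) + q[1] * fu) * (1 - fv) +
                       (q[nu] * (1 - fu) + q[nu + 1] * fu) * fv;
          o[idx] += val * (sad2 / (U * U)) * dbeta;
        }
      }
    }
  }
  return out;
}
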