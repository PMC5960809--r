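#pragma once
#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <algorithm>

// 3-D scalar grid view. Axis order is (axial slice, row, column); the
// physical coordinate of voxel (i,j,k) is origin + index * spacing, in mm.
// Arrays are R column-major: linear index i + n0*(j + n1*k).
struct VolView {
  const double* v;
  int n[3];
  double sp[3], o[3];
};

inline VolView as_vol(const Rcpp::NumericVector& a,
                      const Rcpp::NumericVector& spacing,
                      const Rcpp::NumericVector& origin) {
  VolView V;
  Rcpp::IntegerVector d = a.attr("dim");
  if (d.size() != 3) Rcpp::stop("expected 3-D volume");
  V.v = a.begin();
  for (int i = 0; i < 3; ++i) {
    V.n[i] = d[i];
    V.sp[i] = spacing[i];
    V.o[i] = origin[i];
  }
  return V;
}

inline long long vidx(const VolView& V, int i, int j, int k) {
  return i + (long long)V.n[0] * (j + (long long)V.n[1] * k);
}

// mirror (reflect-without-repeat) index into [0, n)
inline int mirror_idx(int i, int n) {
  if (n == 1) return 0;
  const int p = 2 * n - 2;
  i = ((i % p) + p) % p;
  return i < n ? i : p - i;
}

// cubic B-spline weights for fractional offset t in [0,1); support at
// floor(u)-1 .. floor(u)+2
inline void bspline_w(double t, double* w) {
  const double t2 = t * t, t3 = t2 * t;
  w[0] = (1.0 - 3.0 * t + 3.0 * t2 - t3) / 6.0;
  w[1] = (4.0 - 6.0 * t2 + 3.0 * t3) / 6.0;
  w[2] = (1.0 + 3.0 * t + 3.0 * t2 - 3.0 * t3) / 6.0;
  w[3] = t3 / 6.0;
}

inline void bspline_dw(double t, double* w) {
  const double t2 = t * t;
  w[0] = -(1.0 - 2.0 * t + t2) / 2.0;
  w[1] = (3.0 * t2 - 4.0 * t) / 2.0;
  w[2] = (1.0 + 2.0 * t - 3.0 * t2) / 2.0;
  w[3] = t2 / 2.0;
}

// cubic B-spline kernel beta3(s) and its derivative (signed s)
inline double beta3(double s) {
  s = std::fabs(s);
  if (s >= 2.0) return 0.0;
  if (s >= 1.0) {
    const double u = 2.0 - s;
    return u * u * u / 6.0;
  }
  return 2.0 / 3.0 - s * s + s * s * s / 2.0;
}

inline double beta3_d(double s) {
  const double a = std::fabs(s);
  if (a >= 2.0) return 0.0;
  double d;
  if (a >= 1.0) {
    const double u = 2.0 - a;
    d = -u * u / 2.0;
  } else {
    d = -2.0 * a + 1.5 * a * a;
  }
  return s >= 0.0 ? d : -d;
}

// Trilinear interpolation; optional physical-space gradient. Returns false
// when the point lies outside the volume's physical extent.
inline bool interp_tri(const VolView& V, const double* p, double* val,
                       double* g) {
  double t[3];
  int b[3];
  for (int a = 0; a < 3; ++a) {
    const double u = (p[a] - V.o[a]) / V.sp[a];
    if (!(u >= 0.0 && u <= V.n[a] - 1)) return false;
    int bb = (int)std::floor(u);
    if (bb > V.n[a] - 2) bb = V.n[a] - 2;
    if (bb < 0) bb = 0;
    b[a] = bb;
    t[a] = (V.n[a] == 1) ? 0.0 : u - bb;
  }
  double c[2][2][2];
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k) {
        const int ii = std::min(b[0] + i, V.n[0] - 1);
        const int jj = std::min(b[1] + j, V.n[1] - 1);
        const int kk = std::min(b[2] + k, V.n[2] - 1);
        c[i][j][k] = V.v[vidx(V, ii, jj, kk)];
      }
  const double w0[2] = {1.0 - t[0], t[0]};
  const double w1[2] = {1.0 - t[1], t[1]};
  const double w2[2] = {1.0 - t[2], t[2]};
  double s = 0.0, g0 = 0.0, g1 = 0.0, g2 = 0.0;
  for (int i = 0; i < 2; ++i)
    for (int j = 0; j < 2; ++j)
      for (int k = 0; k < 2; ++k) {
        const double cv = c[i][j][k];
        s += cv * w0[i] * w1[j] * w2[k];
        g0 += cv * (i ? 1.0 : -1.0) * w1[j] * w2[k];
        g1 += cv * w0[i] * (j ? 1.0 : -1.0) * w2[k];
        g2 += cv * w0[i] * w1[j] * (k ? 1.0 : -1.0);
      }
  *val = s;
  if (g) {
    g[0] = g0 / V.sp[0];
    g[1] = g1 / V.sp[1];
    g[2] = g2 / V.sp[2];
  }
  return true;
}

// Cubic B-spline interpolation on a PREFILTERED coefficient volume; optional
// physical-space gradient.
inline bool interp_cubic(const VolView& V, const double* p, double* val,
                         double* g) {
  double w[3][4], dw[3][4];
  int fl[3];
  for (int a = 0; a < 3; ++a) {
    const double u = (p[a] - V.o[a]) / V.sp[a];
    if (!(u >= 0.0 && u <= V.n[a] - 1)) return false;
    fl[a] = (int)std::floor(u);
    const double t = u - fl[a];
    bspline_w(t, w[a]);
    if (g) bspline_dw(t, dw[a]);
  }
  double s = 0.0, g0 = 0.0, g1 = 0.0, g2 = 0.0;
  for (int i = 0; i < 4; ++i) {
    const int ii = mirror_idx(fl[0] - 1 + i, V.n[0]);
    for (int j = 0; j < 4; ++j) {
      const int jj = mirror_idx(fl[1] - 1 + j, V.n[1]);
      for (int k = 0; k < 4; ++k) {
        const int kk = mirror_idx(fl[2] - 1 + k, V.n[2]);
        const double cv = V.v[vidx(V, ii, jj, kk)];
        const double w12 = w[1][j] * w[2][k];
        s += cv * w[0][i] * w12;
        if (g) {
          g0 += cv * dw[0][i] * w12;
          g1 += cv * w[0][i] * dw[1][j] * w[2][k];
          g2 += cv * w[0][i] * w[1][j] * dw[2][k];
        }
      }
    }
  }
  *val = s;
  if (g) {
    g[0] = g0 / V.sp[0];
    g[1] = g1 / V.sp[1];
    g[2] = g2 / V.sp[2];
  }
  return true;
}

inline bool interp_any(const VolView& V, int order, const double* p,
                       double* val, double* g) {
  return order == 3 ? interp_cubic(V, p, val, g) : interp_tri(V, p, val, g);
}
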