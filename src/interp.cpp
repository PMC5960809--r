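#include "vol.h"
using namespace Rcpp;

// ---- cubic B-spline prefilter (recursive, mirror boundaries) -------------

static void prefilter_line(double* c, int n, long long stride) {
  if (n <= 1) return;
  const double z = std::sqrt(3.0) - 2.0;  // pole of the cubic B-spline
  const double lambda = 6.0;
  for (int i = 0; i < n; ++i) c[i * stride] *= lambda;
  // causal init under mirror boundaries: truncated series when the line is
  // long enough, otherwise the exact closed form
  const int horizon = (int)std::ceil(std::log(1e-12) / std::log(std::fabs(z)));
  double sum;
  if (horizon < n) {
    sum = c[0];
    double zn = z;
    for (int i = 1; i < horizon; ++i) {
      sum += zn * c[i * stride];
      zn *= z;
    }
  } else {
    double zn = z, iz = 1.0 / z;
    double z2n = std::pow(z, (double)(n - 1));
    sum = c[0] + z2n * c[(n - 1) * stride];
    z2n *= z2n * iz;
    for (int i = 1; i <= n - 2; ++i) {
      sum += (zn + z2n) * c[i * stride];
      zn *= z;
      z2n *= iz;
    }
    sum /= (1.0 - zn * zn);
  }
  c[0] = sum;
  for (int i = 1; i < n; ++i) c[i * stride] += z * c[(i - 1) * stride];
  c[(n - 1) * stride] =
      (z / (z * z - 1.0)) * (c[(n - 1) * stride] + z * c[(n - 2) * stride]);
  for (int i = n - 2; i >= 0; --i)
    c[i * stride] = z * (c[(i + 1) * stride] - c[i * stride]);
}

// [[Rcpp::export]]
NumericVector cpp_bspline_prefilter(NumericVector arr) {
  IntegerVector d = arr.attr("dim");
  if (d.size() != 3) stop("expected 3-D volume");
  NumericVector out = clone(arr);
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  double* p = out.begin();
  // axis 0
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      prefilter_line(p + (long long)n0 * (j + (long long)n1 * k), n0, 1);
  // axis 1
  for (int k = 0; k < n2; ++k)
    for (int i = 0; i < n0; ++i)
      prefilter_line(p + i + (long long)n0 * n1 * k, n1, n0);
  // axis 2
  for (int j = 0; j < n1; ++j)
    for (int i = 0; i < n0; ++i)
      prefilter_line(p + i + (long long)n0 * j, n2, (long long)n0 * n1);
  out.attr("dim") = d;
  return out;
}

// ---- separable Gaussian smoothing (sigma in voxels, reflected edges) -----

static void smooth_axis(const double* in, double* out, int n0, int n1, int n2,
                        int axis, const std::vector<double>& kern) {
  const int r = ((int)kern.size() - 1) / 2;
  const long long s0 = 1, s1 = n0, s2 = (long long)n0 * n1;
  const long long strides[3] = {s0, s1, s2};
  const int dims[3] = {n0, n1, n2};
  const long long sa = strides[axis];
  const int na = dims[axis];
  int oa1 = (axis + 1) % 3, oa2 = (axis + 2) % 3;
  for (int b = 0; b < dims[oa1]; ++b) {
    for (int c = 0; c < dims[oa2]; ++c) {
      const long long base = b * strides[oa1] + c * strides[oa2];
      for (int i = 0; i < na; ++i) {
        double acc = 0.0;
        for (int t = -r; t <= r; ++t) {
          const int ii = mirror_idx(i + t, na);
          acc += kern[t + r] * in[base + ii * sa];
        }
        out[base + i * sa] = acc;
      }
    }
  }
}

// [[Rcpp::export]]
NumericVector cpp_gauss_smooth(NumericVector arr, NumericVector sigma_vox) {
  IntegerVector d = arr.attr("dim");
  if (d.size() != 3) stop("expected 3-D volume");
  NumericVector cur = clone(arr);
  NumericVector tmp(arr.size());
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  for (int axis = 0; axis < 3; ++axis) {
    const double s = sigma_vox[axis];
    if (s <= 0.0) continue;
    const int r = std::max(1, (int)std::ceil(3.5 * s));
    std::vector<double> kern(2 * r + 1);
    double tot = 0.0;
    for (int t = -r; t <= r; ++t) {
      kern[t + r] = std::exp(-0.5 * (t / s) * (t / s));
      tot += kern[t + r];
    }
    for (double& k : kern) k /= tot;
    smooth_axis(cur.begin(), tmp.begin(), n0, n1, n2, axis, kern);
    std::swap(cur, tmp);
  }
  cur.attr("dim") = d;
  return cur;
}

// ---- transform chain ------------------------------------------------------

struct BsplineGrid {
  bool present = false;
  const double* coef = nullptr;
  int gn[3];
  double go[3], gs[3];
};

static BsplineGrid parse_bspline(SEXP bs) {
  BsplineGrid B;
  if (Rf_isNull(bs)) return B;
  List L(bs);
  NumericVector org = L["origin"], sp = L["spacing"];
  IntegerVector dm = L["dim"];
  NumericVector cf = L["coef"];
  B.present = true;
  B.coef = cf.begin();
  for (int a = 0; a < 3; ++a) {
    B.gn[a] = dm[a];
    B.go[a] = org[a];
    B.gs[a] = sp[a];
  }
  return B;
}

// displacement of the B-spline field at x; returns false when the point has
// no full 4x4x4 support (callers treat that as zero displacement or invalid)
static bool bs_disp(const BsplineGrid& B, const double* x, double* u,
                    double w[3][4], int* base) {
  for (int a = 0; a < 3; ++a) {
    const double g = (x[a] - B.go[a]) / B.gs[a];
    const int fl = (int)std::floor(g);
    if (fl - 1 < 0 || fl + 2 > B.gn[a] - 1) return false;
    base[a] = fl;
    bspline_w(g - fl, w[a]);
  }
  u[0] = u[1] = u[2] = 0.0;
  const long long plane = (long long)B.gn[0] * B.gn[1];
  const long long volsz = plane * B.gn[2];
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      const double wij = w[0][i] * w[1][j];
      for (int k = 0; k < 4; ++k) {
        const double wt = wij * w[2][k];
        const long long idx = (base[0] - 1 + i) +
                              (long long)B.gn[0] * (base[1] - 1 + j) +
                              plane * (base[2] - 1 + k);
        u[0] += wt * B.coef[idx];
        u[1] += wt * B.coef[idx + volsz];
        u[2] += wt * B.coef[idx + 2 * volsz];
      }
    }
  return true;
}

// y = M x + b + u(x); u treated as zero where the field has no support
static void chain_point(const double* M, const double* b,
                        const BsplineGrid& B, const double* x, double* y) {
  for (int r = 0; r < 3; ++r)
    y[r] = M[3 * r] * x[0] + M[3 * r + 1] * x[1] + M[3 * r + 2] * x[2] + b[r];
  if (B.present) {
    double u[3], w[3][4];
    int base[3];
    if (bs_disp(B, x, u, w, base)) {
      y[0] += u[0];
      y[1] += u[1];
      y[2] += u[2];
    }
  }
}

// [[Rcpp::export]]
NumericMatrix cpp_transform_points(NumericMatrix pts, NumericMatrix M,
                                   NumericVector b, SEXP bs) {
  BsplineGrid B = parse_bspline(bs);
  double Mm[9], bb[3];
  for (int r = 0; r < 3; ++r) {
    bb[r] = b[r];
    for (int c = 0; c < 3; ++c) Mm[3 * r + c] = M(r, c);
  }
  const int n = pts.nrow();
  NumericMatrix out(n, 3);
  for (int i = 0; i < n; ++i) {
    double x[3] = {pts(i, 0), pts(i, 1), pts(i, 2)}, y[3];
    chain_point(Mm, bb, B, x, y);
    out(i, 0) = y[0];
    out(i, 1) = y[1];
    out(i, 2) = y[2];
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_eval_points(NumericVector vol, NumericVector sp,
                              NumericVector org, int order,
                              NumericMatrix pts) {
  VolView V = as_vol(vol, sp, org);
  const int n = pts.nrow();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double p[3] = {pts(i, 0), pts(i, 1), pts(i, 2)}, val;
    out[i] = interp_any(V, order, p, &val, nullptr) ? val : NA_REAL;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector cpp_resample_chain(NumericVector mov, NumericVector msp,
                                 NumericVector morg, int order,
                                 NumericMatrix M, NumericVector b, SEXP bs,
                                 IntegerVector tdim, NumericVector tsp,
                                 NumericVector torg, double fill) {
  VolView V = as_vol(mov, msp, morg);
  BsplineGrid B = parse_bspline(bs);
  double Mm[9], bb[3];
  for (int r = 0; r < 3; ++r) {
    bb[r] = b[r];
    for (int c = 0; c < 3; ++c) Mm[3 * r + c] = M(r, c);
  }
  const int n0 = tdim[0], n1 = tdim[1], n2 = tdim[2];
  NumericVector out((long long)n0 * n1 * n2);
  double* po = out.begin();
  long long idx = 0;
  for (int k = 0; k < n2; ++k) {
    const double xk = torg[2] + k * tsp[2];
    for (int j = 0; j < n1; ++j) {
      const double xj = torg[1] + j * tsp[1];
      for (int i = 0; i < n0; ++i, ++idx) {
        double x[3] = {torg[0] + i * tsp[0], xj, xk}, y[3], val;
        chain_point(Mm, bb, B, x, y);
        po[idx] = interp_any(V, order, y, &val, nullptr) ? val : fill;
      }
    }
  }
  out.attr("dim") = tdim;
  return out;
}
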