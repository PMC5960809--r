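#include "vol.h"
using namespace Rcpp;

// ---- rotation helpers -----------------------------------------------------

static void rot_axis(int a, double th, double* R) {
  const double c = std::cos(th), s = std::sin(th);
  for (int i = 0; i < 9; ++i) R[i] = (i % 4 == 0) ? 1.0 : 0.0;
  const int i1 = (a + 1) % 3, i2 = (a + 2) % 3;
  R[i1 * 3 + i1] = c;
  R[i1 * 3 + i2] = -s;
  R[i2 * 3 + i1] = s;
  R[i2 * 3 + i2] = c;
}

static void drot_axis(int a, double th, double* R) {
  const double c = std::cos(th), s = std::sin(th);
  for (int i = 0; i < 9; ++i) R[i] = 0.0;
  const int i1 = (a + 1) % 3, i2 = (a + 2) % 3;
  R[i1 * 3 + i1] = -s;
  R[i1 * 3 + i2] = -c;
  R[i2 * 3 + i1] = c;
  R[i2 * 3 + i2] = -s;
}

static void mm3(const double* A, const double* B, double* C) {
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c)
      C[3 * r + c] = A[3 * r] * B[c] + A[3 * r + 1] * B[3 + c] +
                     A[3 * r + 2] * B[6 + c];
}

// R(a0,a1,a2) = Rot0(a0) * Rot1(a1) * Rot2(a2); rotations about the axial,
// row and column axes in that order. Fills R and, optionally, dR/da_j.
// [[Rcpp::export]]
NumericMatrix cpp_euler_matrix(NumericVector angles) {
  double R0[9], R1[9], R2[9], T[9], R[9];
  rot_axis(0, angles[0], R0);
  rot_axis(1, angles[1], R1);
  rot_axis(2, angles[2], R2);
  mm3(R1, R2, T);
  mm3(R0, T, R);
  NumericMatrix out(3, 3);
  for (int r = 0; r < 3; ++r)
    for (int c = 0; c < 3; ++c) out(r, c) = R[3 * r + c];
  return out;
}

static void euler_and_derivs(const double* ang, double* R, double dR[3][9]) {
  double R0[9], R1[9], R2[9], d0[9], d1[9], d2[9], T[9];
  rot_axis(0, ang[0], R0);
  rot_axis(1, ang[1], R1);
  rot_axis(2, ang[2], R2);
  drot_axis(0, ang[0], d0);
  drot_axis(1, ang[1], d1);
  drot_axis(2, ang[2], d2);
  double R12[9];
  mm3(R1, R2, R12);
  mm3(R0, R12, R);
  mm3(d0, R12, dR[0]);
  mm3(d1, R2, T);
  mm3(R0, T, dR[1]);
  mm3(R1, d2, T);
  mm3(R0, T, dR[2]);
}

// ---- B-spline grid (duplicated small helper; layout as in interp.cpp) ----

struct BsGrid {
  bool present = false;
  const double* coef = nullptr;
  int gn[3];
  double go[3], gs[3];
  long long plane = 0, volsz = 0;
};

static BsGrid parse_bs(SEXP bs) {
  BsGrid B;
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
  B.plane = (long long)B.gn[0] * B.gn[1];
  B.volsz = B.plane * B.gn[2];
  return B;
}

static bool bs_disp2(const BsGrid& B, const double* x, double* u,
                     double w[3][4], int* base) {
  for (int a = 0; a < 3; ++a) {
    const double g = (x[a] - B.go[a]) / B.gs[a];
    const int fl = (int)std::floor(g);
    if (fl - 1 < 0 || fl + 2 > B.gn[a] - 1) return false;
    base[a] = fl;
    bspline_w(g - fl, w[a]);
  }
  u[0] = u[1] = u[2] = 0.0;
  for (int i = 0; i < 4; ++i)
    for (int j = 0; j < 4; ++j) {
      const double wij = w[0][i] * w[1][j];
      for (int k = 0; k < 4; ++k) {
        const double wt = wij * w[2][k];
        const long long idx = (base[0] - 1 + i) +
                              (long long)B.gn[0] * (base[1] - 1 + j) +
                              B.plane * (base[2] - 1 + k);
        u[0] += wt * B.coef[idx];
        u[1] += wt * B.coef[idx + B.volsz];
        u[2] += wt * B.coef[idx + 2 * B.volsz];
      }
    }
  return true;
}

// ---- random coordinate sampler -------------------------------------------

// Uniform points over the physical support of `mask` (rejection sampling in
// the supplied physical bounding box); nearest-voxel membership test.
// [[Rcpp::export]]
NumericMatrix cpp_sample_mask_points(LogicalVector mask, NumericVector sp,
                                     NumericVector org, NumericVector lo,
                                     NumericVector hi, int n) {
  IntegerVector d = mask.attr("dim");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  const int* m = mask.begin();
  NumericMatrix out(n, 3);
  RNGScope scope;
  const long long max_tries = 200LL * n + 1000;
  long long tries = 0;
  int got = 0;
  while (got < n && tries < max_tries) {
    ++tries;
    double p[3];
    int vi[3];
    bool ok = true;
    for (int a = 0; a < 3; ++a) {
      p[a] = lo[a] + unif_rand() * (hi[a] - lo[a]);
      const double u = (p[a] - org[a]) / sp[a];
      const int r = (int)std::lround(u);
      const int na = (a == 0 ? n0 : (a == 1 ? n1 : n2));
      if (r < 0 || r >= na) {
        ok = false;
        break;
      }
      vi[a] = r;
    }
    if (!ok) continue;
    if (m[vi[0] + (long long)n0 * (vi[1] + (long long)n1 * vi[2])] != TRUE)
      continue;
    out(got, 0) = p[0];
    out(got, 1) = p[1];
    out(got, 2) = p[2];
    ++got;
  }
  if (got < n) stop("mask sampling failed: region too small");
  return out;
}

// ---- mutual information on paired sample lists ---------------------------

static double mi_from_hist(const std::vector<double>& H, int nb, double n) {
  std::vector<double> pf(nb, 0.0), pm(nb, 0.0);
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < nb; ++j) {
      pf[i] += H[i * nb + j];
      pm[j] += H[i * nb + j];
    }
  double mi = 0.0;
  for (int i = 0; i < nb; ++i)
    for (int j = 0; j < nb; ++j) {
      const double p = H[i * nb + j] / n;
      if (p > 0.0) mi += p * std::log(p / ((pf[i] / n) * (pm[j] / n)));
    }
  return mi;
}

// window: 3 = cubic B-spline Parzen (the optimizer's estimator),
//         0 = plain zero-order histogram
// [[Rcpp::export]]
double cpp_mi_samples(NumericVector f, NumericVector m, int nbins,
                      int window) {
  const int n = f.size();
  if (n == 0) return 0.0;
  double fmin = f[0], fmax = f[0], mmin = m[0], mmax = m[0];
  for (int i = 0; i < n; ++i) {
    fmin = std::min(fmin, f[i]);
    fmax = std::max(fmax, f[i]);
    mmin = std::min(mmin, m[i]);
    mmax = std::max(mmax, m[i]);
  }
  if (fmax - fmin < 1e-12 || mmax - mmin < 1e-12) return 0.0;
  std::vector<double> H((size_t)nbins * nbins, 0.0);
  if (window == 0) {
    for (int i = 0; i < n; ++i) {
      int bi = (int)((f[i] - fmin) / (fmax - fmin) * nbins);
      int bj = (int)((m[i] - mmin) / (mmax - mmin) * nbins);
      bi = std::min(bi, nbins - 1);
      bj = std::min(bj, nbins - 1);
      H[(size_t)bi * nbins + bj] += 1.0;
    }
  } else {
    const double sf = (nbins - 4) / (fmax - fmin);
    const double sm = (nbins - 4) / (mmax - mmin);
    for (int i = 0; i < n; ++i) {
      double uf = 1.0 + (f[i] - fmin) * sf;
      double um = 1.0 + (m[i] - mmin) * sm;
      uf = std::min(uf, nbins - 3 - 1e-9);
      um = std::min(um, nbins - 3 - 1e-9);
      const int kf = (int)std::floor(uf), km = (int)std::floor(um);
      double wf[4], wm[4];
      bspline_w(uf - kf, wf);
      bspline_w(um - km, wm);
      for (int a = 0; a < 4; ++a)
        for (int b = 0; b < 4; ++b)
          H[(size_t)(kf - 1 + a) * nbins + (km - 1 + b)] += wf[a] * wm[b];
    }
  }
  return mi_from_hist(H, nbins, (double)n);
}

// marginal Parzen (or histogram) entropy of one sample list, in nats
// [[Rcpp::export]]
double cpp_entropy_samples(NumericVector x, int nbins, int window) {
  const int n = x.size();
  if (n == 0) return 0.0;
  double xmin = x[0], xmax = x[0];
  for (int i = 0; i < n; ++i) {
    xmin = std::min(xmin, x[i]);
    xmax = std::max(xmax, x[i]);
  }
  if (xmax - xmin < 1e-12) return 0.0;
  std::vector<double> h(nbins, 0.0);
  if (window == 0) {
    for (int i = 0; i < n; ++i) {
      int b = (int)((x[i] - xmin) / (xmax - xmin) * nbins);
      h[std::min(b, nbins - 1)] += 1.0;
    }
  } else {
    const double s = (nbins - 4) / (xmax - xmin);
    for (int i = 0; i < n; ++i) {
      double u = 1.0 + (x[i] - xmin) * s;
      u = std::min(u, nbins - 3 - 1e-9);
      const int k = (int)std::floor(u);
      double w[4];
      bspline_w(u - k, w);
      for (int a = 0; a < 4; ++a) h[k - 1 + a] += w[a];
    }
  }
  double H = 0.0;
  for (int b = 0; b < nbins; ++b) {
    const double p = h[b] / n;
    if (p > 0.0) H -= p * std::log(p);
  }
  return H;
}

// ---- MI value + analytic gradient for one transform stage ----------------

// stage: 0 none (value only, uses global M,b and optional bs)
//        1 rigid  (params: 3 Euler angles, 3 translations; about `center`)
//        2 affine (params: 3x3 row-major, 3 translations; about `center`)
//        3 bspline (coefficients come in through `bs`; gradient over them;
//                   global M,b frozen)
// pts are fixed-space sample points (the fixed image is interpolated
// there); for rigid/affine stages the frozen earlier global transform
// (preM, preb) is applied to each point before the stage acts on it.
// [[Rcpp::export]]
List cpp_mi_grad(NumericVector fvol, NumericVector fsp, NumericVector forg,
                 int forder, NumericVector mvol, NumericVector msp,
                 NumericVector morg, int morder, NumericMatrix pts,
                 NumericMatrix preM, NumericVector preb,
                 NumericMatrix globalM, NumericVector globalb, SEXP bs,
                 int stage, NumericVector params, NumericVector center,
                 int nbins, bool want_grad, NumericVector range) {
  VolView F = as_vol(fvol, fsp, forg);
  VolView Mv = as_vol(mvol, msp, morg);
  BsGrid B = parse_bs(bs);
  const int n = pts.nrow();

  double R[9], dR[3][9], cen[3] = {0, 0, 0}, tr[3] = {0, 0, 0};
  double GM[9], Gb[3], PM[9], Pb[3];
  for (int r = 0; r < 3; ++r) {
    Gb[r] = globalb[r];
    Pb[r] = preb[r];
    for (int c = 0; c < 3; ++c) {
      GM[3 * r + c] = globalM(r, c);
      PM[3 * r + c] = preM(r, c);
    }
  }
  if (stage == 1) {
    double ang[3] = {params[0], params[1], params[2]};
    euler_and_derivs(ang, R, dR);
    for (int a = 0; a < 3; ++a) {
      tr[a] = params[3 + a];
      cen[a] = center[a];
    }
  } else if (stage == 2) {
    for (int i = 0; i < 9; ++i) R[i] = params[i];
    for (int a = 0; a < 3; ++a) {
      tr[a] = params[9 + a];
      cen[a] = center[a];
    }
  }

  int npar = 0;
  if (want_grad) {
    if (stage == 1) npar = 6;
    else if (stage == 2) npar = 12;
    else if (stage == 3) npar = 3 * (int)B.volsz;
  }

  // per-valid-sample storage
  std::vector<double> fv, mv, gx, xc;  // gx: 3/sample, xc: 3/sample (x-cen)
  std::vector<double> bw;              // 12/sample (bspline weights)
  std::vector<int> bbase;              // 3/sample
  fv.reserve(n);
  mv.reserve(n);
  if (want_grad) gx.reserve(3 * n);

  for (int s = 0; s < n; ++s) {
    double x[3] = {pts(s, 0), pts(s, 1), pts(s, 2)};
    double fval;
    if (!interp_any(F, forder, x, &fval, nullptr)) continue;
    double y[3];
    double w[3][4];
    int base[3] = {0, 0, 0};
    double xs[3] = {x[0], x[1], x[2]};  // stage-input point
    if (stage == 1 || stage == 2) {
      for (int r = 0; r < 3; ++r)
        xs[r] = PM[3 * r] * x[0] + PM[3 * r + 1] * x[1] +
                PM[3 * r + 2] * x[2] + Pb[r];
      for (int r = 0; r < 3; ++r)
        y[r] = R[3 * r] * (xs[0] - cen[0]) +
               R[3 * r + 1] * (xs[1] - cen[1]) +
               R[3 * r + 2] * (xs[2] - cen[2]) + cen[r] + tr[r];
    } else {
      for (int r = 0; r < 3; ++r)
        y[r] = GM[3 * r] * x[0] + GM[3 * r + 1] * x[1] + GM[3 * r + 2] * x[2] +
               Gb[r];
      if (B.present) {
        double u[3];
        if (!bs_disp2(B, x, u, w, base)) {
          if (stage == 3) continue;  // needs full support for the gradient
        } else {
          y[0] += u[0];
          y[1] += u[1];
          y[2] += u[2];
        }
      }
    }
    double mval, g[3];
    if (!interp_any(Mv, morder, y, &mval, want_grad ? g : nullptr)) continue;
    fv.push_back(fval);
    mv.push_back(mval);
    if (want_grad) {
      gx.push_back(g[0]);
      gx.push_back(g[1]);
      gx.push_back(g[2]);
      if (stage == 1 || stage == 2) {
        xc.push_back(xs[0] - cen[0]);
        xc.push_back(xs[1] - cen[1]);
        xc.push_back(xs[2] - cen[2]);
      } else if (stage == 3) {
        for (int a = 0; a < 3; ++a)
          for (int q = 0; q < 4; ++q) bw.push_back(w[a][q]);
        bbase.push_back(base[0]);
        bbase.push_back(base[1]);
        bbase.push_back(base[2]);
      }
    }
  }

  const int nv = (int)fv.size();
  NumericVector grad(npar);
  if (nv == 0)
    return List::create(_["value"] = 0.0, _["grad"] = grad, _["n_valid"] = 0);

  double fmin, fmax, mmin, mmax;
  if (range.size() == 4) {  // frozen per-stage intensity range
    fmin = range[0];
    fmax = range[1];
    mmin = range[2];
    mmax = range[3];
  } else {
    fmin = fv[0]; fmax = fv[0]; mmin = mv[0]; mmax = mv[0];
    for (int i = 0; i < nv; ++i) {
      fmin = std::min(fmin, fv[i]);
      fmax = std::max(fmax, fv[i]);
      mmin = std::min(mmin, mv[i]);
      mmax = std::max(mmax, mv[i]);
    }
  }
  if (fmax - fmin < 1e-12 || mmax - mmin < 1e-12)
    return List::create(_["value"] = 0.0, _["grad"] = grad,
                        _["n_valid"] = nv);

  const double sf = (nbins - 4) / (fmax - fmin);
  const double sm = (nbins - 4) / (mmax - mmin);
  std::vector<double> H((size_t)nbins * nbins, 0.0);
  std::vector<double> uf(nv), um(nv);
  std::vector<char> mclamp(nv, 0);
  for (int i = 0; i < nv; ++i) {
    double a = 1.0 + (fv[i] - fmin) * sf;
    double b = 1.0 + (mv[i] - mmin) * sm;
    // with a frozen range, values outside it are clamped and carry no
    // derivative; with a per-call range every sample lies inside
    if (range.size() == 4 && (b < 1.0 || b > nbins - 3 - 1e-9))
      mclamp[i] = 1;
    uf[i] = std::min(std::max(a, 1.0), nbins - 3 - 1e-9);
    um[i] = std::min(std::max(b, 1.0), nbins - 3 - 1e-9);
    const int kf = (int)std::floor(uf[i]), km = (int)std::floor(um[i]);
    double wf[4], wm[4];
    bspline_w(uf[i] - kf, wf);
    bspline_w(um[i] - km, wm);
    for (int a2 = 0; a2 < 4; ++a2)
      for (int b2 = 0; b2 < 4; ++b2)
        H[(size_t)(kf - 1 + a2) * nbins + (km - 1 + b2)] += wf[a2] * wm[b2];
  }
  std::vector<double> pf(nbins, 0.0), pm(nbins, 0.0);
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      pf[i] += H[i * nbins + j];
      pm[j] += H[i * nbins + j];
    }
  double mi = 0.0;
  for (int i = 0; i < nbins; ++i)
    for (int j = 0; j < nbins; ++j) {
      const double p = H[i * nbins + j] / nv;
      if (p > 0.0)
        mi += p * std::log(p / ((pf[i] / nv) * (pm[j] / nv)));
    }

  if (want_grad && npar > 0) {
    // W(i,j) = log(p(i,j)/p_M(j)); dMI/dmu = sum_ij dp/dmu * W
    std::vector<double> W((size_t)nbins * nbins, 0.0);
    for (int i = 0; i < nbins; ++i)
      for (int j = 0; j < nbins; ++j) {
        const double p = H[i * nbins + j];
        if (p > 0.0) W[i * nbins + j] = std::log(p / pm[j]);
      }
    double* gr = grad.begin();
    for (int i = 0; i < nv; ++i) {
      if (mclamp[i]) continue;  // clamped sample: zero derivative w.r.t. mu
      const int kf = (int)std::floor(uf[i]), km = (int)std::floor(um[i]);
      double wf[4], dwm[4];
      bspline_w(uf[i] - kf, wf);
      bspline_dw(um[i] - km, dwm);
      double acc = 0.0;
      for (int a = 0; a < 4; ++a) {
        const double* Wr = &W[(size_t)(kf - 1 + a) * nbins + (km - 1)];
        acc += wf[a] * (dwm[0] * Wr[0] + dwm[1] * Wr[1] + dwm[2] * Wr[2] +
                        dwm[3] * Wr[3]);
      }
      const double coef = acc * sm / nv;
      const double g0 = gx[3 * i], g1 = gx[3 * i + 1], g2 = gx[3 * i + 2];
      if (stage == 1) {
        const double x0 = xc[3 * i], x1 = xc[3 * i + 1], x2 = xc[3 * i + 2];
        for (int a = 0; a < 3; ++a) {
          const double* D = dR[a];
          const double d0 = D[0] * x0 + D[1] * x1 + D[2] * x2;
          const double d1 = D[3] * x0 + D[4] * x1 + D[5] * x2;
          const double d2 = D[6] * x0 + D[7] * x1 + D[8] * x2;
          gr[a] += coef * (g0 * d0 + g1 * d1 + g2 * d2);
        }
        gr[3] += coef * g0;
        gr[4] += coef * g1;
        gr[5] += coef * g2;
      } else if (stage == 2) {
        const double x0 = xc[3 * i], x1 = xc[3 * i + 1], x2 = xc[3 * i + 2];
        const double gg[3] = {g0, g1, g2};
        const double xx[3] = {x0, x1, x2};
        for (int r = 0; r < 3; ++r)
          for (int c = 0; c < 3; ++c) gr[3 * r + c] += coef * gg[r] * xx[c];
        gr[9] += coef * g0;
        gr[10] += coef * g1;
        gr[11] += coef * g2;
      } else if (stage == 3) {
        const double* w = &bw[12 * i];
        const int b0 = bbase[3 * i], b1 = bbase[3 * i + 1],
                  b2 = bbase[3 * i + 2];
        for (int a = 0; a < 4; ++a) {
          const double w0 = w[a];
          for (int b = 0; b < 4; ++b) {
            const double w01 = w0 * w[4 + b];
            for (int c = 0; c < 4; ++c) {
              const double wt = coef * w01 * w[8 + c];
              const long long idx = (b0 - 1 + a) +
                                    (long long)B.gn[0] * (b1 - 1 + b) +
                                    B.plane * (b2 - 1 + c);
              gr[idx] += wt * g0;
              gr[idx + B.volsz] += wt * g1;
              gr[idx + 2 * B.volsz] += wt * g2;
            }
          }
        }
      }
    }
  }
  return List::create(_["value"] = mi, _["grad"] = grad, _["n_valid"] = nv);
}
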