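#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// 3-D connected-component labeling (6 or 26 connectivity), iterative BFS.
// [[Rcpp::export]]
IntegerVector cpp_label3d(LogicalVector mask, int connectivity) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("expected 3-D mask");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  const long long nv = (long long)n0 * n1 * n2;
  IntegerVector lab(nv, 0);
  const int* m = mask.begin();
  int* L = lab.begin();

  std::vector<int> off0, off1, off2;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        if (connectivity == 6 && std::abs(a) + std::abs(b) + std::abs(c) != 1)
          continue;
        off0.push_back(a);
        off1.push_back(b);
        off2.push_back(c);
      }
  const int noff = (int)off0.size();

  int ncomp = 0;
  std::vector<long long> stack;
  for (long long s = 0; s < nv; ++s) {
    if (m[s] != TRUE || L[s] != 0) continue;
    ++ncomp;
    L[s] = ncomp;
    stack.clear();
    stack.push_back(s);
    while (!stack.empty()) {
      const long long cur = stack.back();
      stack.pop_back();
      const int i = (int)(cur % n0);
      const int j = (int)((cur / n0) % n1);
      const int k = (int)(cur / ((long long)n0 * n1));
      for (int t = 0; t < noff; ++t) {
        const int ii = i + off0[t], jj = j + off1[t], kk = k + off2[t];
        if (ii < 0 || ii >= n0 || jj < 0 || jj >= n1 || kk < 0 || kk >= n2)
          continue;
        const long long q = ii + (long long)n0 * (jj + (long long)n1 * kk);
        if (m[q] == TRUE && L[q] == 0) {
          L[q] = ncomp;
          stack.push_back(q);
        }
      }
    }
  }
  lab.attr("dim") = d;
  lab.attr("ncomp") = ncomp;
  return lab;
}

static LogicalVector ball_op(LogicalVector mask, NumericVector radius_vox,
                             bool dilate) {
  IntegerVector d = mask.attr("dim");
  if (d.size() != 3) stop("expected 3-D mask");
  const int n0 = d[0], n1 = d[1], n2 = d[2];
  const double r0 = std::max(radius_vox[0], 1e-9);
  const double r1 = std::max(radius_vox[1], 1e-9);
  const double r2 = std::max(radius_vox[2], 1e-9);
  std::vector<int> off0, off1, off2;
  const int R0 = (int)std::floor(r0), R1 = (int)std::floor(r1),
            R2 = (int)std::floor(r2);
  for (int a = -R0; a <= R0; ++a)
    for (int b = -R1; b <= R1; ++b)
      for (int c = -R2; c <= R2; ++c) {
        const double q = (a / r0) * (a / r0) + (b / r1) * (b / r1) +
                         (c / r2) * (c / r2);
        if (q <= 1.0) {
          off0.push_back(a);
          off1.push_back(b);
          off2.push_back(c);
        }
      }
  const int noff = (int)off0.size();
  const long long nv = (long long)n0 * n1 * n2;
  LogicalVector out(nv);
  const int* m = mask.begin();
  int* po = out.begin();
  long long idx = 0;
  for (int k = 0; k < n2; ++k)
    for (int j = 0; j < n1; ++j)
      for (int i = 0; i < n0; ++i, ++idx) {
        bool hit = dilate ? false : true;
        for (int t = 0; t < noff; ++t) {
          const int ii = i + off0[t], jj = j + off1[t], kk = k + off2[t];
          bool inside = !(ii < 0 || ii >= n0 || jj < 0 || jj >= n1 || kk < 0 ||
                          kk >= n2);
          const bool v =
              inside &&
              m[ii + (long long)n0 * (jj + (long long)n1 * kk)] == TRUE;
          if (dilate) {
            if (v) {
              hit = true;
              break;
            }
          } else {
            if (!v) {
              hit = false;
              break;
            }
          }
        }
        po[idx] = hit ? TRUE : FALSE;
      }
  out.attr("dim") = d;
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_dilate(LogicalVector mask, NumericVector radius_vox) {
  return ball_op(mask, radius_vox, true);
}

// [[Rcpp::export]]
LogicalVector cpp_erode(LogicalVector mask, NumericVector radius_vox) {
  return ball_op(mask, radius_vox, false);
}
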