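#include <Rcpp.h>
#include <algorithm>
#include <queue>
#include <vector>
using namespace Rcpp;

// Index helpers: arrays arrive as R column-major vectors with dim (nx, ny, nz).
static inline R_xlen_t idx3(int i, int j, int k, int nx, int ny) {
  return (R_xlen_t)i + (R_xlen_t)nx * ((R_xlen_t)j + (R_xlen_t)ny * (R_xlen_t)k);
}

// Resample a source volume onto a target grid. M is a 3x4 matrix (column-major,
// 12 values) mapping target 0-based voxel indices to source continuous 0-based
// indices. interp: 0 = nearest neighbour, 1 = trilinear. Outside -> fill.
// [[Rcpp::export]]
NumericVector cpp_resample3d(NumericVector src, IntegerVector sdim,
                             IntegerVector tdim, NumericVector M,
                             int interp, double fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const int tx = tdim[0], ty = tdim[1], tz = tdim[2];
  NumericVector out((R_xlen_t)tx * ty * tz);
  const double m00 = M[0], m10 = M[1], m20 = M[2];
  const double m01 = M[3], m11 = M[4], m21 = M[5];
  const double m02 = M[6], m12 = M[7], m22 = M[8];
  const double m03 = M[9], m13 = M[10], m23 = M[11];
  R_xlen_t p = 0;
  for (int k = 0; k < tz; ++k) {
    for (int j = 0; j < ty; ++j) {
      for (int i = 0; i < tx; ++i, ++p) {
        const double u = m00 * i + m01 * j + m02 * k + m03;
        const double v = m10 * i + m11 * j + m12 * k + m13;
        const double w = m20 * i + m21 * j + m22 * k + m23;
        if (interp == 0) {
          const int iu = (int)std::lround(u), iv = (int)std::lround(v),
                    iw = (int)std::lround(w);
          if (iu < 0 || iu >= sx || iv < 0 || iv >= sy || iw < 0 || iw >= sz) {
            out[p] = fill;
          } else {
            out[p] = src[idx3(iu, iv, iw, sx, sy)];
          }
        } else {
          const int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
                    k0 = (int)std::floor(w);
          if (i0 < -1 || i0 > sx - 1 || j0 < -1 || j0 > sy - 1 ||
              k0 < -1 || k0 > sz - 1) {
            out[p] = fill;
            continue;
          }
          const double fu = u - i0, fv = v - j0, fw = w - k0;
          double acc = 0.0;
          for (int dk = 0; dk <= 1; ++dk) {
            const int kk = k0 + dk;
            const double wk = dk ? fw : 1.0 - fw;
            for (int dj = 0; dj <= 1; ++dj) {
              const int jj = j0 + dj;
              const double wj = dj ? fv : 1.0 - fv;
              for (int di = 0; di <= 1; ++di) {
                const int ii = i0 + di;
                const double wi = di ? fu : 1.0 - fu;
                const double wgt = wi * wj * wk;
                if (wgt == 0.0) continue;
                double val = fill;
                if (ii >= 0 && ii < sx && jj >= 0 && jj < sy && kk >= 0 && kk < sz)
                  val = src[idx3(ii, jj, kk, sx, sy)];
                acc += wgt * val;
              }
            }
          }
          out[p] = acc;
        }
      }
    }
  }
  return out;
}

// Cubic-box median filter with truncated windows at the edges.
// [[Rcpp::export]]
NumericVector cpp_median3d(NumericVector x, IntegerVector dim, int radius) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  NumericVector out((R_xlen_t)nx * ny * nz);
  std::vector<double> buf;
  buf.reserve((2 * radius + 1) * (2 * radius + 1) * (2 * radius + 1));
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    const int k0 = std::max(0, k - radius), k1 = std::min(nz - 1, k + radius);
    for (int j = 0; j < ny; ++j) {
      const int j0 = std::max(0, j - radius), j1 = std::min(ny - 1, j + radius);
      for (int i = 0; i < nx; ++i, ++p) {
        const int i0 = std::max(0, i - radius), i1 = std::min(nx - 1, i + radius);
        buf.clear();
        for (int kk = k0; kk <= k1; ++kk)
          for (int jj = j0; jj <= j1; ++jj)
            for (int ii = i0; ii <= i1; ++ii)
              buf.push_back(x[idx3(ii, jj, kk, nx, ny)]);
        const size_t n = buf.size();
        const size_t mid = n / 2;
        std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
        double med = buf[mid];
        if (n % 2 == 0) {
          std::nth_element(buf.begin(), buf.begin() + mid - 1,
                           buf.begin() + mid);
          med = 0.5 * (med + buf[mid - 1]);
        }
        out[p] = med;
      }
    }
  }
  return out;
}

// 6-connectivity binary erosion/dilation; out-of-grid treated as background.
// [[Rcpp::export]]
LogicalVector cpp_morph3d(LogicalVector x, IntegerVector dim, bool dilate) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  LogicalVector out((R_xlen_t)nx * ny * nz);
  R_xlen_t p = 0;
  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i, ++p) {
        bool c = x[p];
        bool any_n = false, all_n = true;
        const int di[6] = {-1, 1, 0, 0, 0, 0};
        const int dj[6] = {0, 0, -1, 1, 0, 0};
        const int dk[6] = {0, 0, 0, 0, -1, 1};
        for (int q = 0; q < 6; ++q) {
          const int ii = i + di[q], jj = j + dj[q], kk = k + dk[q];
          bool v = false;
          if (ii >= 0 && ii < nx && jj >= 0 && jj < ny && kk >= 0 && kk < nz)
            v = x[idx3(ii, jj, kk, nx, ny)];
          any_n = any_n || v;
          all_n = all_n && v;
        }
        out[p] = dilate ? (c || any_n) : (c && all_n);
      }
    }
  }
  return out;
}

// Label 6-connected foreground components; returns integer component labels
// (0 = background), components numbered in scan order.
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector x, IntegerVector dim) {
  const int nx = dim[0], ny = dim[1], nz = dim[2];
  const R_xlen_t n = (R_xlen_t)nx * ny * nz;
  IntegerVector lab(n, 0);
  int next = 0;
  std::queue<R_xlen_t> q;
  const int di[6] = {-1, 1, 0, 0, 0, 0};
  const int dj[6] = {0, 0, -1, 1, 0, 0};
  const int dk[6] = {0, 0, 0, 0, -1, 1};
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!x[s] || lab[s]) continue;
    lab[s] = ++next;
    q.push(s);
    while (!q.empty()) {
      const R_xlen_t c = q.front();
      q.pop();
      const int i = (int)(c % nx);
      const int j = (int)((c / nx) % ny);
      const int k = (int)(c / ((R_xlen_t)nx * ny));
      for (int t = 0; t < 6; ++t) {
        const int ii = i + di[t], jj = j + dj[t], kk = k + dk[t];
        if (ii < 0 || ii >= nx || jj < 0 || jj >= ny || kk < 0 || kk >= nz)
          continue;
        const R_xlen_t u = idx3(ii, jj, kk, nx, ny);
        if (x[u] && !lab[u]) {
          lab[u] = next;
          q.push(u);
        }
      }
    }
  }
  return lab;
}

// Sample the source volume at transformed positions of selected target
// voxels only (registration hot path). idx is an n x 3 matrix of 0-based
// target voxel indices.
// [[Rcpp::export]]
NumericVector cpp_sample_points(NumericVector src, IntegerVector sdim,
                                IntegerMatrix idx, NumericVector M,
                                double fill) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const R_xlen_t n = idx.nrow();
  NumericVector out(n);
  const double m00 = M[0], m10 = M[1], m20 = M[2];
  const double m01 = M[3], m11 = M[4], m21 = M[5];
  const double m02 = M[6], m12 = M[7], m22 = M[8];
  const double m03 = M[9], m13 = M[10], m23 = M[11];
  for (R_xlen_t r = 0; r < n; ++r) {
    const int i = idx(r, 0), j = idx(r, 1), k = idx(r, 2);
    const double u = m00 * i + m01 * j + m02 * k + m03;
    const double v = m10 * i + m11 * j + m12 * k + m13;
    const double w = m20 * i + m21 * j + m22 * k + m23;
    const int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
    if (i0 < -1 || i0 > sx - 1 || j0 < -1 || j0 > sy - 1 ||
        k0 < -1 || k0 > sz - 1) {
      out[r] = fill;
      continue;
    }
    const double fu = u - i0, fv = v - j0, fw = w - k0;
    double acc = 0.0;
    for (int dk = 0; dk <= 1; ++dk) {
      const int kk = k0 + dk;
      const double wk = dk ? fw : 1.0 - fw;
      for (int dj = 0; dj <= 1; ++dj) {
        const int jj = j0 + dj;
        const double wj = dj ? fv : 1.0 - fv;
        for (int di = 0; di <= 1; ++di) {
          const int ii = i0 + di;
          const double wi = di ? fu : 1.0 - fu;
          const double wgt = wi * wj * wk;
          if (wgt == 0.0) continue;
          double val = fill;
          if (ii >= 0 && ii < sx && jj >= 0 && jj < sy && kk >= 0 && kk < sz)
            val = src[idx3(ii, jj, kk, sx, sy)];
          acc += wgt * val;
        }
      }
    }
    out[r] = acc;
  }
  return out;
}

// Fused registration objective: sample the moving image at transformed
// positions of the fixed foreground voxels and accumulate the joint
// histogram against precomputed fixed-image bins in one pass. Returns the
// normalized mutual information (H(a)+H(b))/H(a,b), or NA when degenerate.
// [[Rcpp::export]]
double cpp_nmi_objective(NumericVector src, IntegerVector sdim,
                         IntegerMatrix idx, NumericVector M,
                         IntegerVector fixed_bin, int nbins) {
  const int sx = sdim[0], sy = sdim[1], sz = sdim[2];
  const R_xlen_t n = idx.nrow();
  if (n < 100) return NA_REAL;
  std::vector<double> b(n);
  const double m00 = M[0], m10 = M[1], m20 = M[2];
  const double m01 = M[3], m11 = M[4], m21 = M[5];
  const double m02 = M[6], m12 = M[7], m22 = M[8];
  const double m03 = M[9], m13 = M[10], m23 = M[11];
  double bmin = R_PosInf, bmax = R_NegInf;
  for (R_xlen_t r = 0; r < n; ++r) {
    const int i = idx(r, 0), j = idx(r, 1), k = idx(r, 2);
    const double u = m00 * i + m01 * j + m02 * k + m03;
    const double v = m10 * i + m11 * j + m12 * k + m13;
    const double w = m20 * i + m21 * j + m22 * k + m23;
    const int i0 = (int)std::floor(u), j0 = (int)std::floor(v),
              k0 = (int)std::floor(w);
    double val = 0.0;
    if (i0 >= -1 && i0 <= sx - 1 && j0 >= -1 && j0 <= sy - 1 &&
        k0 >= -1 && k0 <= sz - 1) {
      const double fu = u - i0, fv = v - j0, fw = w - k0;
      for (int dk = 0; dk <= 1; ++dk) {
        const int kk = k0 + dk;
        const double wk = dk ? fw : 1.0 - fw;
        for (int dj = 0; dj <= 1; ++dj) {
          const int jj = j0 + dj;
          const double wj = dj ? fv : 1.0 - fv;
          for (int di = 0; di <= 1; ++di) {
            const int ii = i0 + di;
            const double wi = di ? fu : 1.0 - fu;
            const double wgt = wi * wj * wk;
            if (wgt == 0.0) continue;
            if (ii >= 0 && ii < sx && jj >= 0 && jj < sy && kk >= 0 && kk < sz)
              val += wgt * src[idx3(ii, jj, kk, sx, sy)];
          }
        }
      }
    }
    b[r] = val;
    if (val < bmin) bmin = val;
    if (val > bmax) bmax = val;
  }
  if (!(bmax > bmin)) return NA_REAL;
  std::vector<double> joint((size_t)nbins * nbins, 0.0);
  std::vector<double> pa(nbins, 0.0), pb(nbins, 0.0);
  const double scale = nbins / (bmax - bmin);
  for (R_xlen_t r = 0; r < n; ++r) {
    int ib = (int)((b[r] - bmin) * scale);
    if (ib >= nbins) ib = nbins - 1;
    const int ia = fixed_bin[r] - 1;
    joint[(size_t)ia + (size_t)nbins * ib] += 1.0;
    pa[ia] += 1.0;
    pb[ib] += 1.0;
  }
  double ha = 0.0, hb = 0.0, hab = 0.0;
  const double inv = 1.0 / (double)n;
  for (int i = 0; i < nbins; ++i) {
    if (pa[i] > 0) { const double p = pa[i] * inv; ha -= p * std::log(p); }
    if (pb[i] > 0) { const double p = pb[i] * inv; hb -= p * std::log(p); }
  }
  for (size_t i = 0; i < joint.size(); ++i)
    if (joint[i] > 0) { const double p = joint[i] * inv; hab -= p * std::log(p); }
  if (hab <= 0) return NA_REAL;
  return (ha + hb) / hab;
}
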