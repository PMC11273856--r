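#include <Rcpp.h>
using namespace Rcpp;

// Minimum-cost path across the columns of `cost` (rows = depth states).
// Allowed band per column is [lo, hi] (1-based); vertical moves between
// neighbouring columns are limited to max_step pixels and charged
// penalty * |step|. Returns the 1-based depth of the path in each column.
// [[Rcpp::export]]
IntegerVector dp_min_path_cpp(NumericMatrix cost, IntegerVector lo,
                              IntegerVector hi, int max_step, double penalty) {
  const int nz = cost.nrow(), na = cost.ncol();
  const double BIG = 1e18;
  NumericMatrix D(nz, na);
  IntegerMatrix P(nz, na);
  for (int z = 0; z < nz; ++z) {
    bool in = (z + 1 >= lo[0]) && (z + 1 <= hi[0]);
    D(z, 0) = in ? cost(z, 0) : BIG;
  }
  for (int a = 1; a < na; ++a) {
    for (int z = 0; z < nz; ++z) {
      if (z + 1 < lo[a] || z + 1 > hi[a]) { D(z, a) = BIG; P(z, a) = 0; continue; }
      double best = BIG; int arg = 0;
      for (int s = -max_step; s <= max_step; ++s) {
        int zp = z + s;
        if (zp < 0 || zp >= nz) continue;
        double c = D(zp, a - 1);
        if (c >= BIG) continue;
        c += penalty * std::abs(s);
        if (c < best) { best = c; arg = s; }
      }
      D(z, a) = (best >= BIG) ? BIG : cost(z, a) + best;
      P(z, a) = arg;
    }
  }
  IntegerVector path(na);
  int zbest = 0; double vbest = BIG;
  for (int z = 0; z < nz; ++z)
    if (D(z, na - 1) < vbest) { vbest = D(z, na - 1); zbest = z; }
  path[na - 1] = zbest + 1;
  for (int a = na - 1; a > 0; --a) {
    zbest = zbest + P(zbest, a);
    path[a - 1] = zbest + 1;
  }
  return path;
}

// Separable box (moving-average) filter with edge replication; wr along
// rows (depth), wc along columns. Widths must be odd (1 = no smoothing).
// [[Rcpp::export]]
NumericMatrix box_smooth_cpp(NumericMatrix m, int wr, int wc) {
  const int n = m.nrow(), p = m.ncol();
  NumericMatrix tmp(n, p), out(n, p);
  const int hr = (wr - 1) / 2, hc = (wc - 1) / 2;
  // rows (within each column)
  if (hr == 0) {
    tmp = clone(m);
  } else {
    std::vector<double> S(n + 1);
    for (int j = 0; j < p; ++j) {
      S[0] = 0.0;
      for (int i = 0; i < n; ++i) S[i + 1] = S[i] + m(i, j);
      for (int i = 0; i < n; ++i) {
        int a = i - hr, b = i + hr;       // inclusive window
        double s = 0.0;
        int a2 = a < 0 ? 0 : a, b2 = b > n - 1 ? n - 1 : b;
        s = S[b2 + 1] - S[a2];
        if (a < 0) s += (-a) * m(0, j);
        if (b > n - 1) s += (b - (n - 1)) * m(n - 1, j);
        tmp(i, j) = s / wr;
      }
    }
  }
  // columns (within each row)
  if (hc == 0) return tmp;
  std::vector<double> S(p + 1);
  for (int i = 0; i < n; ++i) {
    S[0] = 0.0;
    for (int j = 0; j < p; ++j) S[j + 1] = S[j] + tmp(i, j);
    for (int j = 0; j < p; ++j) {
      int a = j - hc, b = j + hc;
      double s = 0.0;
      int a2 = a < 0 ? 0 : a, b2 = b > p - 1 ? p - 1 : b;
      s = S[b2 + 1] - S[a2];
      if (a < 0) s += (-a) * tmp(i, 0);
      if (b > p - 1) s += (b - (p - 1)) * tmp(i, p - 1);
      out(i, j) = s / wc;
    }
  }
  return out;
}

// Trilinear-interpolated mean-squared difference between a moving volume
// sampled at (x, y, z) (1-based fractional voxel coordinates) and reference
// values; out-of-bounds queries are skipped. Returns (mse, fraction valid).
// [[Rcpp::export]]
NumericVector mse_interp_cpp(NumericVector arr, IntegerVector dim,
                             NumericVector x, NumericVector y,
                             NumericVector z, NumericVector ref) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = x.size();
  const double* a = arr.begin();
  double acc = 0.0;
  R_xlen_t cnt = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    if (!(xi >= 1 && xi <= d1 && yi >= 1 && yi <= d2 && zi >= 1 && zi <= d3))
      continue;
    int x0 = (int)xi, y0 = (int)yi, z0 = (int)zi;
    if (x0 > d1 - 1) x0 = d1 - 1;
    if (y0 > d2 - 1) y0 = d2 - 1;
    if (z0 > d3 - 1) z0 = d3 - 1;
    if (d1 == 1) x0 = 1; if (d2 == 1) y0 = 1; if (d3 == 1) z0 = 1;
    const double fx = xi - x0, fy = yi - y0, fz = zi - z0;
    const int x1 = x0 < d1 ? x0 + 1 : x0;
    const int y1 = y0 < d2 ? y0 + 1 : y0;
    const int z1 = z0 < d3 ? z0 + 1 : z0;
    // 0-based linear offsets
    const R_xlen_t o000 = (x0 - 1) + (R_xlen_t)d1 * ((y0 - 1) + (R_xlen_t)d2 * (z0 - 1));
    const R_xlen_t o100 = (x1 - 1) + (R_xlen_t)d1 * ((y0 - 1) + (R_xlen_t)d2 * (z0 - 1));
    const R_xlen_t o010 = (x0 - 1) + (R_xlen_t)d1 * ((y1 - 1) + (R_xlen_t)d2 * (z0 - 1));
    const R_xlen_t o001 = (x0 - 1) + (R_xlen_t)d1 * ((y0 - 1) + (R_xlen_t)d2 * (z1 - 1));
    const R_xlen_t o110 = (x1 - 1) + (R_xlen_t)d1 * ((y1 - 1) + (R_xlen_t)d2 * (z0 - 1));
    const R_xlen_t o101 = (x1 - 1) + (R_xlen_t)d1 * ((y0 - 1) + (R_xlen_t)d2 * (z1 - 1));
    const R_xlen_t o011 = (x0 - 1) + (R_xlen_t)d1 * ((y1 - 1) + (R_xlen_t)d2 * (z1 - 1));
    const R_xlen_t o111 = (x1 - 1) + (R_xlen_t)d1 * ((y1 - 1) + (R_xlen_t)d2 * (z1 - 1));
    const double v =
      a[o000] * (1 - fx) * (1 - fy) * (1 - fz) + a[o100] * fx * (1 - fy) * (1 - fz) +
      a[o010] * (1 - fx) * fy * (1 - fz) + a[o001] * (1 - fx) * (1 - fy) * fz +
      a[o110] * fx * fy * (1 - fz) + a[o101] * fx * (1 - fy) * fz +
      a[o011] * (1 - fx) * fy * fz + a[o111] * fx * fy * fz;
    const double r = v - ref[i];
    acc += r * r;
    ++cnt;
  }
  NumericVector out(2);
  out[0] = cnt > 0 ? acc / cnt : R_PosInf;
  out[1] = n > 0 ? (double)cnt / (double)n : 0.0;
  return out;
}

// Trilinear interpolation of a volume at 1-based fractional coordinates;
// out-of-bounds queries return NA.
// [[Rcpp::export]]
NumericVector interp3_cpp(NumericVector arr, IntegerVector dim,
                          NumericVector x, NumericVector y, NumericVector z) {
  const int d1 = dim[0], d2 = dim[1], d3 = dim[2];
  const R_xlen_t n = x.size();
  const double* a = arr.begin();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i) {
    const double xi = x[i], yi = y[i], zi = z[i];
    if (!(xi >= 1 && xi <= d1 && yi >= 1 && yi <= d2 && zi >= 1 && zi <= d3)) {
      out[i] = NA_REAL;
      continue;
    }
    int x0 = (int)xi, y0 = (int)yi, z0 = (int)zi;
    if (x0 > d1 - 1) x0 = d1 - 1;
    if (y0 > d2 - 1) y0 = d2 - 1;
    if (z0 > d3 - 1) z0 = d3 - 1;
    if (d1 == 1) x0 = 1; if (d2 == 1) y0 = 1; if (d3 == 1) z0 = 1;
    const double fx = xi - x0, fy = yi - y0, fz = zi - z0;
    const int x1 = x0 < d1 ? x0 + 1 : x0;
    const int y1 = y0 < d2 ? y0 + 1 : y0;
    const int z1 = z0 < d3 ? z0 + 1 : z0;
    #define OFF(xx, yy, zz) ((xx - 1) + (R_xlen_t)d1 * ((yy - 1) + (R_xlen_t)d2 * (zz - 1)))
    out[i] =
      a[OFF(x0, y0, z0)] * (1 - fx) * (1 - fy) * (1 - fz) +
      a[OFF(x1, y0, z0)] * fx * (1 - fy) * (1 - fz) +
      a[OFF(x0, y1, z0)] * (1 - fx) * fy * (1 - fz) +
      a[OFF(x0, y0, z1)] * (1 - fx) * (1 - fy) * fz +
      a[OFF(x1, y1, z0)] * fx * fy * (1 - fz) +
      a[OFF(x1, y0, z1)] * fx * (1 - fy) * fz +
      a[OFF(x0, y1, z1)] * (1 - fx) * fy * fz +
      a[OFF(x1, y1, z1)] * fx * fy * fz;
    #undef OFF
  }
  return out;
}

// Perona-Malik anisotropic diffusion: explicit 4-neighbour scheme with
// conduction exp(-(g/kappa)^2) and reflective borders.
// [[Rcpp::export]]
NumericMatrix pm_diffusion_cpp(NumericMatrix img, int n_iter, double kappa,
                               double lambda) {
  const int n = img.nrow(), p = img.ncol();
  NumericMatrix cur = clone(img), nxt(n, p);
  const double ik2 = 1.0 / (kappa * kappa);
  for (int it = 0; it < n_iter; ++it) {
    for (int j = 0; j < p; ++j) {
      const int jw = j > 0 ? j - 1 : 0, je = j < p - 1 ? j + 1 : p - 1;
      for (int i = 0; i < n; ++i) {
        const int in_ = i > 0 ? i - 1 : 0, is = i < n - 1 ? i + 1 : n - 1;
        const double c = cur(i, j);
        const double dN = cur(in_, j) - c, dS = cur(is, j) - c;
        const double dW = cur(i, jw) - c, dE = cur(i, je) - c;
        nxt(i, j) = c + lambda * (std::exp(-dN * dN * ik2) * dN +
                                  std::exp(-dS * dS * ik2) * dS +
                                  std::exp(-dW * dW * ik2) * dW +
                                  std::exp(-dE * dE * ik2) * dE);
      }
    }
    std::swap(cur, nxt);
  }
  return cur;
}
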