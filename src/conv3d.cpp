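#include <Rcpp.h>
using namespace Rcpp;

// 3D convolution kernels for small U-Nets.
//
// Feature maps are numeric arrays with dim = (d1, d2, d3, C), column-major,
// first index fastest. Kernels are (k, k, k, Cin, Cout) with odd k and
// zero ("same") padding. Work is row-blocked: for each output row along the
// contiguous first dimension, all k^3 taps are applied while the row sits in
// cache, with the first-dimension boundary folded into the loop limits.

// [[Rcpp::export]]
NumericVector cpp_conv3d_fwd(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3];
  const int k = wd[0], cout = wd[4];
  if (wd[3] != cin) stop("kernel input channels (%d) do not match input (%d)", (int)wd[3], cin);
  const int p = (k - 1) / 2;
  const size_t vol = (size_t)d1 * d2 * d3;
  NumericVector y(vol * cout);
  y.attr("dim") = IntegerVector::create(d1, d2, d3, cout);
  const double *px = REAL(x), *pw = REAL(w);
  double *py = REAL(y);
  for (int co = 0; co < cout; ++co) {
    double *yc = py + vol * co;
    const double bias = b[co];
    for (size_t i = 0; i < vol; ++i) yc[i] = bias;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + vol * ci;
      const double *wk = pw + (size_t)k * k * k * (ci + (size_t)cin * co);
      for (int i3 = 0; i3 < d3; ++i3) {
        for (int i2 = 0; i2 < d2; ++i2) {
          double *orow = yc + (size_t)d1 * (i2 + (size_t)d2 * i3);
          for (int a3 = 0; a3 < k; ++a3) {
            const int j3 = i3 + a3 - p;
            if (j3 < 0 || j3 >= d3) continue;
            for (int a2 = 0; a2 < k; ++a2) {
              const int j2 = i2 + a2 - p;
              if (j2 < 0 || j2 >= d2) continue;
              const double *xrow = xc + (size_t)d1 * (j2 + (size_t)d2 * j3);
              for (int a1 = 0; a1 < k; ++a1) {
                const double wv = wk[a1 + k * (a2 + k * a3)];
                if (wv == 0.0) continue;
                const int s = a1 - p;
                const int l = std::max(0, -s), h = std::min(d1 - 1, d1 - 1 - s);
                const double *xs = xrow + s;
                for (int i1 = l; i1 <= h; ++i1) orow[i1] += wv * xs[i1];
              }
            }
          }
        }
      }
    }
  }
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_conv3d_bwd_input(NumericVector gy, NumericVector w) {
  IntegerVector gd = gy.attr("dim"), wd = w.attr("dim");
  const int d1 = gd[0], d2 = gd[1], d3 = gd[2], cout = gd[3];
  const int k = wd[0], cin = wd[3];
  const int p = (k - 1) / 2;
  const size_t vol = (size_t)d1 * d2 * d3;
  NumericVector gx(vol * cin);
  gx.attr("dim") = IntegerVector::create(d1, d2, d3, cin);
  const double *pg = REAL(gy), *pw = REAL(w);
  double *px = REAL(gx);
  // gx(i, ci) = sum_{co, a} gy(i - (a - p), co) * w(a, ci, co):
  // a correlation with the reflected kernel — same row-blocked pattern.
  for (int ci = 0; ci < cin; ++ci) {
    double *xc = px + vol * ci;
    for (int co = 0; co < cout; ++co) {
      const double *gc = pg + vol * co;
      const double *wk = pw + (size_t)k * k * k * (ci + (size_t)cin * co);
      for (int i3 = 0; i3 < d3; ++i3) {
        for (int i2 = 0; i2 < d2; ++i2) {
          double *orow = xc + (size_t)d1 * (i2 + (size_t)d2 * i3);
          for (int a3 = 0; a3 < k; ++a3) {
            const int j3 = i3 - (a3 - p);
            if (j3 < 0 || j3 >= d3) continue;
            for (int a2 = 0; a2 < k; ++a2) {
              const int j2 = i2 - (a2 - p);
              if (j2 < 0 || j2 >= d2) continue;
              const double *grow = gc + (size_t)d1 * (j2 + (size_t)d2 * j3);
              for (int a1 = 0; a1 < k; ++a1) {
                const double wv = wk[a1 + k * (a2 + k * a3)];
                if (wv == 0.0) continue;
                const int s = -(a1 - p);
                const int l = std::max(0, -s), h = std::min(d1 - 1, d1 - 1 - s);
                const double *gs = grow + s;
                for (int i1 = l; i1 <= h; ++i1) orow[i1] += wv * gs[i1];
              }
            }
          }
        }
      }
    }
  }
  return gx;
}

// [[Rcpp::export]]
List cpp_conv3d_bwd_weights(NumericVector x, NumericVector gy, int k) {
  IntegerVector xd = x.attr("dim"), gd = gy.attr("dim");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3], cout = gd[3];
  const int p = (k - 1) / 2;
  const int kk = k * k * k;
  const size_t vol = (size_t)d1 * d2 * d3;
  NumericVector gw((size_t)kk * cin * cout), gb(cout);
  gw.attr("dim") = IntegerVector::create(k, k, k, cin, cout);
  const double *px = REAL(x), *pg = REAL(gy);
  double *pw = REAL(gw);
  std::vector<double> acc(kk);
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + vol * co;
    double bs = 0.0;
    for (size_t i = 0; i < vol; ++i) bs += gc[i];
    gb[co] = bs;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + vol * ci;
      std::fill(acc.begin(), acc.end(), 0.0);
      // gw(a) = sum_i x(i + a - p) * gy(i); accumulate all taps per gy row
      for (int i3 = 0; i3 < d3; ++i3) {
        for (int i2 = 0; i2 < d2; ++i2) {
          const double *grow = gc + (size_t)d1 * (i2 + (size_t)d2 * i3);
          for (int a3 = 0; a3 < k; ++a3) {
            const int j3 = i3 + a3 - p;
            if (j3 < 0 || j3 >= d3) continue;
            for (int a2 = 0; a2 < k; ++a2) {
              const int j2 = i2 + a2 - p;
              if (j2 < 0 || j2 >= d2) continue;
              const double *xrow = xc + (size_t)d1 * (j2 + (size_t)d2 * j3);
              for (int a1 = 0; a1 < k; ++a1) {
                const int s = a1 - p;
                const int l = std::max(0, -s), h = std::min(d1 - 1, d1 - 1 - s);
                const double *xs = xrow + s;
                double dot = 0.0;
                for (int i1 = l; i1 <= h; ++i1) dot += xs[i1] * grow[i1];
                acc[a1 + k * (a2 + k * a3)] += dot;
              }
            }
          }
        }
      }
      double *wk = pw + (size_t)kk * (ci + (size_t)cin * co);
      for (int a = 0; a < kk; ++a) wk[a] = acc[a];
    }
  }
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// [[Rcpp::export]]
List cpp_maxpool3d_fwd(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], C = xd[3];
  if (d1 % 2 || d2 % 2 || d3 % 2) stop("max-pooling needs even spatial dimensions");
  const int o1 = d1 / 2, o2 = d2 / 2, o3 = d3 / 2;
  const size_t vol = (size_t)d1 * d2 * d3, ovol = (size_t)o1 * o2 * o3;
  NumericVector y(ovol * C);
  IntegerVector idx(ovol * C);
  y.attr("dim") = IntegerVector::create(o1, o2, o3, C);
  const double *px = REAL(x);
  double *py = REAL(y);
  int *pi = INTEGER(idx);
  for (int c = 0; c < C; ++c) {
    const double *xc = px + vol * c;
    double *yc = py + ovol * c;
    int *ic = pi + ovol * c;
    for (int i3 = 0; i3 < o3; ++i3)
      for (int i2 = 0; i2 < o2; ++i2)
        for (int i1 = 0; i1 < o1; ++i1) {
          double best = -1e300; size_t barg = 0;
          for (int b3 = 0; b3 < 2; ++b3)
            for (int b2 = 0; b2 < 2; ++b2)
              for (int b1 = 0; b1 < 2; ++b1) {
                size_t j = (size_t)(2 * i1 + b1) +
                  (size_t)d1 * ((2 * i2 + b2) + (size_t)d2 * (2 * i3 + b3));
                if (xc[j] > best) { best = xc[j]; barg = j; }
              }
          size_t o = (size_t)i1 + (size_t)o1 * (i2 + (size_t)o2 * i3);
          yc[o] = best;
          ic[o] = (int)(barg + vol * c); // 0-based linear index into x
        }
  }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector cpp_maxpool3d_bwd(NumericVector gy, IntegerVector idx, IntegerVector xdim) {
  const size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector gx(n);
  gx.attr("dim") = xdim;
  double *px = REAL(gx);
  const double *pg = REAL(gy);
  const int *pi = INTEGER(idx);
  const R_xlen_t m = gy.size();
  for (R_xlen_t i = 0; i < m; ++i) px[pi[i]] += pg[i];
  return gx;
}
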