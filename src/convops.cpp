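// Dense convolution / pooling kernels for the autodiff core.
// Layout: feature maps are column-major R arrays (X, Y, Z, C); 2D maps use
// Z = 1. Kernels are (k1, k2, k3, Cin, Cout). Strides and zero-paddings are
// per-axis. Batch size is always one (the training protocol fixes it).
//
// Loops hoist the kernel weight and restrict output indices to the range
// whose source voxels are in bounds, so the innermost loop streams over
// contiguous memory without branch checks.
#include <Rcpp.h>
using namespace Rcpp;

static inline R_xlen_t idx4(int i1, int i2, int i3, int c,
                            int d1, int d2, int d3) {
  return i1 + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * (i3 + (R_xlen_t)d3 * c));
}

// Valid output range [jlo, jhi) for source index i = j*s - p + q in [0, d).
static inline void outRange(int d, int s, int p, int q, int o,
                            int &jlo, int &jhi) {
  int lo = p - q;                 // j*s >= lo
  jlo = (lo <= 0) ? 0 : (lo + s - 1) / s;
  int hi = d - 1 - q + p;         // j*s <= hi
  jhi = (hi < 0) ? 0 : hi / s + 1;
  if (jhi > o) jhi = o;
  if (jlo > jhi) jlo = jhi;
}

// [[Rcpp::export]]
NumericVector conv3d_fwd_cpp(NumericVector x, IntegerVector xd,
                             NumericVector w, IntegerVector wd,
                             NumericVector b,
                             IntegerVector stride, IntegerVector pad) {
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], cout = wd[4];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = (d1 + 2 * p1 - k1) / s1 + 1;
  const int o2 = (d2 + 2 * p2 - k2) / s2 + 1;
  const int o3 = (d3 + 2 * p3 - k3) / s3 + 1;
  NumericVector y((R_xlen_t)o1 * o2 * o3 * cout);
  const double *px = x.begin(), *pw = w.begin();
  double *py = y.begin();
  for (int co = 0; co < cout; ++co) {
    double *yc = py + (R_xlen_t)o1 * o2 * o3 * co;
    const double bias = (b.size() == 1) ? b[0] : b[co];
    for (R_xlen_t t = 0; t < (R_xlen_t)o1 * o2 * o3; ++t) yc[t] = bias;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + (R_xlen_t)d1 * d2 * d3 * ci;
      for (int q3 = 0; q3 < k3; ++q3) {
        int j3lo, j3hi; outRange(d3, s3, p3, q3, o3, j3lo, j3hi);
        for (int q2 = 0; q2 < k2; ++q2) {
          int j2lo, j2hi; outRange(d2, s2, p2, q2, o2, j2lo, j2hi);
          for (int q1 = 0; q1 < k1; ++q1) {
            int j1lo, j1hi; outRange(d1, s1, p1, q1, o1, j1lo, j1hi);
            const double wv = pw[q1 + (R_xlen_t)k1 * (q2 + (R_xlen_t)k2 *
                              (q3 + (R_xlen_t)k3 * (ci + (R_xlen_t)cin * co)))];
            if (wv == 0.0) continue;
            for (int j3 = j3lo; j3 < j3hi; ++j3) {
              const int i3 = j3 * s3 - p3 + q3;
              for (int j2 = j2lo; j2 < j2hi; ++j2) {
                const int i2 = j2 * s2 - p2 + q2;
                const double *xrow = xc + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
                double *yrow = yc + (R_xlen_t)o1 * (j2 + (R_xlen_t)o2 * j3);
                const int off = -p1 + q1;
                if (s1 == 1) {
                  for (int j1 = j1lo; j1 < j1hi; ++j1)
                    yrow[j1] += wv * xrow[j1 + off];
                } else {
                  for (int j1 = j1lo; j1 < j1hi; ++j1)
                    yrow[j1] += wv * xrow[j1 * s1 + off];
                }
              }
            }
          }
        }
      }
    }
  }
  y.attr("dim") = IntegerVector::create(o1, o2, o3, cout);
  return y;
}

// [[Rcpp::export]]
NumericVector conv3d_bwd_x_cpp(NumericVector gy, IntegerVector yd,
                               NumericVector w, IntegerVector wd,
                               IntegerVector xd,
                               IntegerVector stride, IntegerVector pad) {
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], cout = wd[4];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = yd[0], o2 = yd[1], o3 = yd[2];
  NumericVector gx((R_xlen_t)d1 * d2 * d3 * cin);
  const double *pg = gy.begin(), *pw = w.begin();
  double *px = gx.begin();
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + (R_xlen_t)o1 * o2 * o3 * co;
    for (int ci = 0; ci < cin; ++ci) {
      double *xc = px + (R_xlen_t)d1 * d2 * d3 * ci;
      for (int q3 = 0; q3 < k3; ++q3) {
        int j3lo, j3hi; outRange(d3, s3, p3, q3, o3, j3lo, j3hi);
        for (int q2 = 0; q2 < k2; ++q2) {
          int j2lo, j2hi; outRange(d2, s2, p2, q2, o2, j2lo, j2hi);
          for (int q1 = 0; q1 < k1; ++q1) {
            int j1lo, j1hi; outRange(d1, s1, p1, q1, o1, j1lo, j1hi);
            const double wv = pw[q1 + (R_xlen_t)k1 * (q2 + (R_xlen_t)k2 *
                              (q3 + (R_xlen_t)k3 * (ci + (R_xlen_t)cin * co)))];
            if (wv == 0.0) continue;
            for (int j3 = j3lo; j3 < j3hi; ++j3) {
              const int i3 = j3 * s3 - p3 + q3;
              for (int j2 = j2lo; j2 < j2hi; ++j2) {
                const int i2 = j2 * s2 - p2 + q2;
                double *xrow = xc + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
                const double *grow = gc + (R_xlen_t)o1 * (j2 + (R_xlen_t)o2 * j3);
                const int off = -p1 + q1;
                if (s1 == 1) {
                  for (int j1 = j1lo; j1 < j1hi; ++j1)
                    xrow[j1 + off] += wv * grow[j1];
                } else {
                  for (int j1 = j1lo; j1 < j1hi; ++j1)
                    xrow[j1 * s1 + off] += wv * grow[j1];
                }
              }
            }
          }
        }
      }
    }
  }
  gx.attr("dim") = xd;
  return gx;
}

// [[Rcpp::export]]
List conv3d_bwd_w_cpp(NumericVector x, IntegerVector xd,
                      NumericVector gy, IntegerVector yd,
                      IntegerVector wd,
                      IntegerVector stride, IntegerVector pad) {
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], cin = xd[3];
  const int k1 = wd[0], k2 = wd[1], k3 = wd[2], cout = wd[4];
  const int s1 = stride[0], s2 = stride[1], s3 = stride[2];
  const int p1 = pad[0], p2 = pad[1], p3 = pad[2];
  const int o1 = yd[0], o2 = yd[1], o3 = yd[2];
  NumericVector gw((R_xlen_t)k1 * k2 * k3 * cin * cout);
  NumericVector gb(cout);
  const double *px = x.begin(), *pg = gy.begin();
  double *pw = gw.begin();
  for (int co = 0; co < cout; ++co) {
    const double *gc = pg + (R_xlen_t)o1 * o2 * o3 * co;
    double bacc = 0.0;
    for (R_xlen_t t = 0; t < (R_xlen_t)o1 * o2 * o3; ++t) bacc += gc[t];
    gb[co] = bacc;
    for (int ci = 0; ci < cin; ++ci) {
      const double *xc = px + (R_xlen_t)d1 * d2 * d3 * ci;
      for (int q3 = 0; q3 < k3; ++q3) {
        int j3lo, j3hi; outRange(d3, s3, p3, q3, o3, j3lo, j3hi);
        for (int q2 = 0; q2 < k2; ++q2) {
          int j2lo, j2hi; outRange(d2, s2, p2, q2, o2, j2lo, j2hi);
          for (int q1 = 0; q1 < k1; ++q1) {
            int j1lo, j1hi; outRange(d1, s1, p1, q1, o1, j1lo, j1hi);
            double acc = 0.0;
            for (int j3 = j3lo; j3 < j3hi; ++j3) {
              const int i3 = j3 * s3 - p3 + q3;
              for (int j2 = j2lo; j2 < j2hi; ++j2) {
                const int i2 = j2 * s2 - p2 + q2;
                const double *xrow = xc + (R_xlen_t)d1 * (i2 + (R_xlen_t)d2 * i3);
                const double *grow = gc + (R_xlen_t)o1 * (j2 + (R_xlen_t)o2 * j3);
                const int off = -p1 + q1;
                if (s1 == 1) {
                  for (int j1 = j1lo; j1 < j1hi; ++j1)
                    acc += xrow[j1 + off] * grow[j1];
                } else {
                  for (int j1 = j1lo; j1 < j1hi; ++j1)
                    acc += xrow[j1 * s1 + off] * grow[j1];
                }
              }
            }
            pw[q1 + (R_xlen_t)k1 * (q2 + (R_xlen_t)k2 *
               (q3 + (R_xlen_t)k3 * (ci + (R_xlen_t)cin * co)))] = acc;
          }
        }
      }
    }
  }
  gw.attr("dim") = wd;
  return List::create(_["gw"] = gw, _["gb"] = gb);
}

// 2x2 max pooling over the first two axes (Z and C untouched); records the
// linear index of the argmax for exact gradient routing.
// [[Rcpp::export]]
List maxpool2_fwd_cpp(NumericVector x, IntegerVector xd) {
  const int d1 = xd[0], d2 = xd[1], d3 = xd[2], nc = xd[3];
  const int o1 = d1 / 2, o2 = d2 / 2;
  NumericVector y((R_xlen_t)o1 * o2 * d3 * nc);
  IntegerVector am(y.size());
  const double *px = x.begin();
  double *py = y.begin();
  int *pa = am.begin();
  for (int c = 0; c < nc; ++c)
    for (int i3 = 0; i3 < d3; ++i3)
      for (int j2 = 0; j2 < o2; ++j2)
        for (int j1 = 0; j1 < o1; ++j1) {
          double best = R_NegInf; R_xlen_t bi = 0;
          for (int q2 = 0; q2 < 2; ++q2)
            for (int q1 = 0; q1 < 2; ++q1) {
              R_xlen_t ii = idx4(2 * j1 + q1, 2 * j2 + q2, i3, c, d1, d2, d3);
              if (px[ii] > best) { best = px[ii]; bi = ii; }
            }
          R_xlen_t oi = idx4(j1, j2, i3, c, o1, o2, d3);
          py[oi] = best;
          pa[oi] = (int)bi;
        }
  y.attr("dim") = IntegerVector::create(o1, o2, d3, nc);
  return List::create(_["y"] = y, _["argmax"] = am);
}

// [[Rcpp::export]]
NumericVector maxpool2_bwd_cpp(NumericVector gy, IntegerVector argmax,
                               IntegerVector xd) {
  NumericVector gx((R_xlen_t)xd[0] * xd[1] * xd[2] * xd[3]);
  for (R_xlen_t i = 0; i < gy.size(); ++i) gx[argmax[i]] += gy[i];
  gx.attr("dim") = xd;
  return gx;
}
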