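// Hot numeric kernels for the CNN engine. Feature maps are C x (H*W*N)
// matrices whose columns are ordered (h, w, n) with h fastest; a 3x3 "same"
// convolution is, per kernel offset, one GEMM over a contiguous column range
// of the map followed by explicit correction of the columns whose source
// crosses an h- or w-border. K9 is (9*Cin) x Cout with row blocks ordered by
// offset k = 1..9, dh = (k-1) % 3 - 1, dw = (k-1) / 3 - 1.
//
// All entry points take Rcpp objects and wrap them in Armadillo views
// borrowing the R memory (no copies in either direction).
#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
#ifdef __GLIBC__
#include <malloc.h>
// Large feature-map buffers are allocated and freed once per layer call;
// keep glibc from returning them to the kernel between calls.
__attribute__((constructor)) static void tune_allocator() {
  mallopt(M_MMAP_THRESHOLD, 512 * 1024 * 1024);
  mallopt(M_TRIM_THRESHOLD, 512 * 1024 * 1024);
}
#endif
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat borrow(Rcpp::NumericMatrix& X) {
  return mat(X.begin(), X.nrow(), X.ncol(), false, true);
}

// columns (0-based, within [r0, r1]) whose source crosses an h-/w-border
static std::vector<int> bad_cols(int H, int W, int dh, int dw, int r0, int r1) {
  std::vector<int> bad;
  for (int r = r0; r <= r1; ++r) {
    int hw = r % (H * W);
    int h = hw % H;
    int w = hw / H;
    if (h + dh < 0 || h + dh >= H || w + dw < 0 || w + dw >= W)
      bad.push_back(r);
  }
  return bad;
}

// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_conv3_fwd(Rcpp::NumericMatrix Mr, int H, int W, int N,
                                  Rcpp::NumericMatrix K9r,
                                  Rcpp::NumericVector br) {
  mat M = borrow(Mr), K9 = borrow(K9r);
  int C = M.n_rows, Cout = K9.n_cols, HWN = H * W * N;
  Rcpp::NumericMatrix outR(Cout, HWN);
  mat out(outR.begin(), Cout, HWN, false, true);
  vec b(br.begin(), br.size(), false, true);
  out.each_col() = b;
  for (int k = 0; k < 9; ++k) {
    int dh = (k % 3) - 1, dw = (k / 3) - 1;
    int s = dh + dw * H;
    int r0 = std::max(0, -s), r1 = std::min(HWN - 1, HWN - 1 - s);
    if (r0 > r1) continue;
    mat Kk = K9.rows(k * C, (k + 1) * C - 1).t();  // Cout x Cin
    out.cols(r0, r1) += Kk * M.cols(r0 + s, r1 + s);
    // subtract the contributions wrongly added at border columns
    const double *kp = Kk.memptr();
    for (int r : bad_cols(H, W, dh, dw, r0, r1)) {
      const double *x = M.colptr(r + s);
      double *y = out.colptr(r);
      for (int ci = 0; ci < C; ++ci) {
        double xv = x[ci];
        const double *kcol = kp + (size_t)ci * Cout;
        for (int co = 0; co < Cout; ++co) y[co] -= kcol[co] * xv;
      }
    }
  }
  return outR;
}

// [[Rcpp::export]]
Rcpp::List cpp_conv3_bwd(Rcpp::NumericMatrix Mr, Rcpp::NumericMatrix K9r,
                         Rcpp::NumericMatrix dOutr, int H, int W, int N,
                         bool need_dx) {
  mat M = borrow(Mr), K9 = borrow(K9r), dOut = borrow(dOutr);
  int C = M.n_rows, Cout = K9.n_cols, HWN = H * W * N;
  Rcpp::NumericMatrix dK9R(K9.n_rows, K9.n_cols);
  mat dK9(dK9R.begin(), K9.n_rows, K9.n_cols, false, true);
  Rcpp::NumericVector dbR(Cout);
  vec db(dbR.begin(), Cout, false, true);
  db = sum(dOut, 1);
  Rcpp::NumericMatrix dMR(need_dx ? C : 1, need_dx ? HWN : 1);
  mat dM;
  if (need_dx) {
    dM = mat(dMR.begin(), C, HWN, false, true);
    dM.zeros();
  }
  for (int k = 0; k < 9; ++k) {
    int dh = (k % 3) - 1, dw = (k / 3) - 1;
    int s = dh + dw * H;
    int r0 = std::max(0, -s), r1 = std::min(HWN - 1, HWN - 1 - s);
    if (r0 > r1) continue;
    std::vector<int> bad = bad_cols(H, W, dh, dw, r0, r1);
    mat dKk = M.cols(r0 + s, r1 + s) * dOut.cols(r0, r1).t();  // Cin x Cout
    double *dkp = dKk.memptr();
    for (int r : bad) {
      const double *x = M.colptr(r + s);
      const double *d = dOut.colptr(r);
      for (int co = 0; co < Cout; ++co) {
        double dv = d[co];
        double *kcol = dkp + (size_t)co * C;
        for (int ci = 0; ci < C; ++ci) kcol[ci] -= x[ci] * dv;
      }
    }
    dK9.rows(k * C, (k + 1) * C - 1) = dKk;
    if (need_dx) {
      mat KkT = K9.rows(k * C, (k + 1) * C - 1);   // Cin x Cout
      dM.cols(r0 + s, r1 + s) += KkT * dOut.cols(r0, r1);
      const double *kp = KkT.memptr();
      for (int r : bad) {
        const double *d = dOut.colptr(r);
        double *y = dM.colptr(r + s);
        for (int co = 0; co < Cout; ++co) {
          double dv = d[co];
          const double *kcol = kp + (size_t)co * C;
          for (int ci = 0; ci < C; ++ci) y[ci] -= kcol[ci] * dv;
        }
      }
    }
  }
  return Rcpp::List::create(Rcpp::Named("dK") = dK9R,
                            Rcpp::Named("db") = dbR,
                            Rcpp::Named("dM") = dMR);
}

// Fused batch norm + ReLU forward; xhat is recomputed in the backward pass
// from the cached input, so only the activation is materialized here.
// [[Rcpp::export]]
Rcpp::NumericMatrix cpp_bn_relu_fwd(Rcpp::NumericMatrix Mr,
                                    Rcpp::NumericVector gamma,
                                    Rcpp::NumericVector beta,
                                    Rcpp::NumericVector m,
                                    Rcpp::NumericVector invstd) {
  int C = Mr.nrow(); long n = Mr.ncol();
  Rcpp::NumericMatrix outR(C, n);
  const double *mp = Mr.begin(), *gm = gamma.begin(), *bt = beta.begin(),
               *mm = m.begin(), *is = invstd.begin();
  double *op = outR.begin();
  for (long j = 0; j < n; ++j) {
    const double *mcol = mp + j * C;
    double *ocol = op + j * C;
    for (int i = 0; i < C; ++i) {
      double o = (mcol[i] - mm[i]) * is[i] * gm[i] + bt[i];
      ocol[i] = o > 0 ? o : 0.0;
    }
  }
  return outR;
}

// [[Rcpp::export]]
Rcpp::List cpp_bn_relu_bwd(Rcpp::NumericMatrix dOutr, Rcpp::NumericMatrix outr,
                           Rcpp::NumericMatrix Mr, Rcpp::NumericVector m,
                           Rcpp::NumericVector gamma,
                           Rcpp::NumericVector invstd) {
  int C = dOutr.nrow(); long n = dOutr.ncol();
  Rcpp::NumericVector dgamma(C), dbeta(C);
  std::vector<double> s1(C, 0.0), s2(C, 0.0);
  Rcpp::NumericMatrix dMR(C, n);
  const double *dp = dOutr.begin(), *op = outr.begin(), *mp = Mr.begin(),
               *mm = m.begin(), *gm = gamma.begin(), *is = invstd.begin();
  double *dmp = dMR.begin(), *dg = dgamma.begin(), *db = dbeta.begin();
  for (long j = 0; j < n; ++j) {
    const double *dcol = dp + j * C, *ocol = op + j * C, *mcol = mp + j * C;
    double *dmcol = dmp + j * C;
    for (int i = 0; i < C; ++i) {
      double d = ocol[i] > 0 ? dcol[i] : 0.0;  // ReLU gate
      double xh = (mcol[i] - mm[i]) * is[i];
      double dx = d * gm[i];
      dmcol[i] = dx;                            // provisional, scaled below
      dg[i] += d * xh;
      db[i] += d;
      s1[i] += dx;
      s2[i] += dx * xh;
    }
  }
  for (long j = 0; j < n; ++j) {
    const double *mcol = mp + j * C;
    double *dmcol = dmp + j * C;
    for (int i = 0; i < C; ++i) {
      double xh = (mcol[i] - mm[i]) * is[i];
      dmcol[i] = (dmcol[i] - s1[i] / n - xh * s2[i] / n) * is[i];
    }
  }
  return Rcpp::List::create(Rcpp::Named("dM") = dMR,
                            Rcpp::Named("dgamma") = dgamma,
                            Rcpp::Named("dbeta") = dbeta);
}

// Per-channel mean and biased variance in one pass.
// [[Rcpp::export]]
Rcpp::List cpp_row_stats(Rcpp::NumericMatrix Mr) {
  int C = Mr.nrow(); long n = Mr.ncol();
  Rcpp::NumericVector m(C), v(C);
  const double *mp = Mr.begin();
  double *mm = m.begin(), *vv = v.begin();
  for (long j = 0; j < n; ++j) {
    const double *col = mp + j * C;
    for (int i = 0; i < C; ++i) {
      mm[i] += col[i];
      vv[i] += col[i] * col[i];
    }
  }
  for (int i = 0; i < C; ++i) {
    mm[i] /= n;
    vv[i] = vv[i] / n - mm[i] * mm[i];
  }
  return Rcpp::List::create(Rcpp::Named("mean") = m, Rcpp::Named("var") = v);
}
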