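// Low-level kernels for the 2D CNN engine and 3D mask utilities.
// Tensor layout throughout: (H, W, C, N) stored column-major as in R arrays.
#include <RcppArmadillo.h>
#include <queue>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// im2col for kxk "same" convolution with zero padding p = (k-1)/2.
// Layout: (H*W) x (C*k*k), so writes are contiguous down each column and
// the convolution is a single (HW x CKK) * (CKK x Cout) GEMM.
static void im2col(const double* x, int H, int W, int C, int k,
                   arma::mat& col) {
  int p = (k - 1) / 2;
  for (int c = 0; c < C; ++c) {
    const double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        double* dst = col.colptr(c * k * k + dj * k + di);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - p;
          double* d = dst + (size_t)j * H;
          if (sj < 0 || sj >= W) {
            std::fill(d, d + H, 0.0);
            continue;
          }
          const double* src = xc + (size_t)sj * H;
          int lo = std::max(0, p - di);           // i with si in range
          int hi = std::min(H, H + p - di);
          std::fill(d, d + lo, 0.0);
          std::copy(src + lo + di - p, src + hi + di - p, d + lo);
          std::fill(d + hi, d + H, 0.0);
        }
      }
    }
  }
}

// col2im: scatter-add transpose of im2col ((H*W) x (C*k*k) layout).
static void col2im(const arma::mat& col, int H, int W, int C, int k,
                   double* x) {
  int p = (k - 1) / 2;
  std::fill(x, x + (size_t)H * W * C, 0.0);
  for (int c = 0; c < C; ++c) {
    double* xc = x + (size_t)c * H * W;
    for (int dj = 0; dj < k; ++dj) {
      for (int di = 0; di < k; ++di) {
        const double* srcc = col.colptr(c * k * k + dj * k + di);
        for (int j = 0; j < W; ++j) {
          int sj = j + dj - p;
          if (sj < 0 || sj >= W) continue;
          double* dst = xc + (size_t)sj * H;
          const double* s = srcc + (size_t)j * H;
          int lo = std::max(0, p - di);
          int hi = std::min(H, H + p - di);
          for (int i = lo; i < hi; ++i) dst[i + di - p] += s[i];
        }
      }
    }
  }
}

// Forward convolution, kernel k in {1,3,...}, same padding, stride 1.
// x: (H,W,Cin,N); w: (k,k,Cin,Cout); b: length Cout. Returns (H,W,Cout,N).
// [[Rcpp::export]]
NumericVector conv2d_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector out((size_t)H * W * Cout * N);
  out.attr("dim") = IntegerVector::create(H, W, Cout, N);
  arma::mat col(H * W, Cin * k * k);
  for (int n = 0; n < N; ++n) {
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, col);
    arma::mat o(out.begin() + (size_t)n * H * W * Cout, H * W, Cout,
                false, true);
    o = col * Wm;  // (H*W) x Cout, already in output layout
    for (int c = 0; c < Cout; ++c) o.col(c) += b[c];
  }
  return out;
}

// Backward convolution: returns list(dx, dw, db).
// [[Rcpp::export]]
List conv2d_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3];
  int k = wd[0], Cout = wd[3];
  arma::mat Wm(const_cast<double*>(w.begin()), k * k * Cin, Cout, false);
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = IntegerVector::create(H, W, Cin, N);
  arma::mat dWm(k * k * Cin, Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat col(H * W, Cin * k * k);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)n * H * W * Cout;
    arma::mat dym(const_cast<double*>(dyp), H * W, Cout, false);
    im2col(x.begin() + (size_t)n * H * W * Cin, H, W, Cin, k, col);
    dWm += col.t() * dym;                 // (Cin*k*k) x Cout
    db += arma::sum(dym, 0).t();
    arma::mat dcol = dym * Wm.t();        // (H*W) x (Cin*k*k)
    col2im(dcol, H, W, Cin, k, dx.begin() + (size_t)n * H * W * Cin);
  }
  NumericVector dw(wd[0] * wd[1] * wd[2] * wd[3]);
  std::copy(dWm.begin(), dWm.end(), dw.begin());
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Per-channel affine transform y = z * sc[c] + sh[c] for (H,W,C,N) tensors;
// used by batch normalisation to avoid large temporaries in R.
// [[Rcpp::export]]
NumericVector channel_affine(NumericVector z, NumericVector sc,
                             NumericVector sh) {
  IntegerVector zd = z.attr("dim");
  size_t hw = (size_t)zd[0] * zd[1];
  int C = zd[2], N = zd[3];
  NumericVector y(z.size());
  y.attr("dim") = zd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      const double* src = z.begin() + ((size_t)n * C + c) * hw;
      double* dst = y.begin() + ((size_t)n * C + c) * hw;
      double a = sc[c], b = sh[c];
      for (size_t s = 0; s < hw; ++s) dst[s] = src[s] * a + b;
    }
  return y;
}

// ReLU forward in place-ish: returns y and logical mask packed as raw 0/1.
// [[Rcpp::export]]
List relu_fw_cpp(NumericVector z) {
  NumericVector y(z.size());
  y.attr("dim") = z.attr("dim");
  LogicalVector mask(z.size());
  for (R_xlen_t i = 0; i < z.size(); ++i) {
    double v = z[i];
    if (v > 0) { y[i] = v; mask[i] = true; }
  }
  return List::create(_["y"] = y, _["mask"] = mask);
}

// Fused batch-norm backward for dx:
// dx = g_istd[c] * (dy - s1[c]/m - xhat * s2[c]/m).
// [[Rcpp::export]]
NumericVector bn_bw_dx(NumericVector dy, NumericVector xhat,
                       NumericVector s1, NumericVector s2,
                       NumericVector g_istd, double m) {
  IntegerVector zd = dy.attr("dim");
  size_t hw = (size_t)zd[0] * zd[1];
  int C = zd[2], N = zd[3];
  NumericVector dx(dy.size());
  dx.attr("dim") = zd;
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t off = ((size_t)n * C + c) * hw;
      const double* dyp = dy.begin() + off;
      const double* xp = xhat.begin() + off;
      double* out = dx.begin() + off;
      double a = g_istd[c], m1 = s1[c] / m, m2 = s2[c] / m;
      for (size_t s = 0; s < hw; ++s)
        out[s] = a * (dyp[s] - m1 - xp[s] * m2);
    }
  return dx;
}

// 2x2 max pooling, stride 2. Returns list(y, idx) with 1-based argmax
// linear indices into the input array.
// [[Rcpp::export]]
List maxpool2_fw(NumericVector x) {
  IntegerVector xd = x.attr("dim");
  int H = xd[0], W = xd[1], C = xd[2], N = xd[3];
  int Ho = H / 2, Wo = W / 2;
  NumericVector y((size_t)Ho * Wo * C * N);
  IntegerVector idx((size_t)Ho * Wo * C * N);
  y.attr("dim") = IntegerVector::create(Ho, Wo, C, N);
  for (int n = 0; n < N; ++n)
    for (int c = 0; c < C; ++c) {
      size_t xoff = ((size_t)n * C + c) * H * W;
      size_t yoff = ((size_t)n * C + c) * Ho * Wo;
      for (int j = 0; j < Wo; ++j)
        for (int i = 0; i < Ho; ++i) {
          size_t best = xoff + (size_t)(2 * j) * H + 2 * i;
          double bv = x[best];
          size_t cand[3] = {xoff + (size_t)(2 * j) * H + 2 * i + 1,
                            xoff + (size_t)(2 * j + 1) * H + 2 * i,
                            xoff + (size_t)(2 * j + 1) * H + 2 * i + 1};
          for (int q = 0; q < 3; ++q)
            if (x[cand[q]] > bv) { bv = x[cand[q]]; best = cand[q]; }
          y[yoff + (size_t)j * Ho + i] = bv;
          idx[yoff + (size_t)j * Ho + i] = (int)(best + 1);
        }
    }
  return List::create(_["y"] = y, _["idx"] = idx);
}

// [[Rcpp::export]]
NumericVector maxpool2_bw(IntegerVector idx, NumericVector dy,
                          IntegerVector xdim) {
  size_t n = (size_t)xdim[0] * xdim[1] * xdim[2] * xdim[3];
  NumericVector dx(n);
  dx.attr("dim") = xdim;
  for (R_xlen_t s = 0; s < dy.size(); ++s) dx[idx[s] - 1] += dy[s];
  return dx;
}

// Transposed convolution with 2x2 kernel, stride 2 (non-overlapping).
// x: (H,W,Cin,N); w: (2,2,Cin,Cout). Output (2H,2W,Cout,N).
// [[Rcpp::export]]
NumericVector upconv2_fw(NumericVector x, NumericVector w, NumericVector b) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector out((size_t)Ho * Wo * Cout * N);
  out.attr("dim") = IntegerVector::create(Ho, Wo, Cout, N);
  // Wm: Cin x (4*Cout); rows of kernel taps laid out (di,dj) = 4 per Cout.
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          Wm(ci, co * 4 + dj * 2 + di) =
              w[(size_t)((co * Cin + ci) * 2 + dj) * 2 + di];
  for (int n = 0; n < N; ++n) {
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * Cin,
                 H * W, Cin, false);
    arma::mat o = xm * Wm;  // (H*W) x (4*Cout)
    double* op = out.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co)
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          size_t base = (size_t)co * Ho * Wo;
          size_t s = (size_t)j * H + i;
          op[base + (size_t)(2 * j) * Ho + 2 * i]         = o(s, co * 4 + 0) + b[co];
          op[base + (size_t)(2 * j) * Ho + 2 * i + 1]     = o(s, co * 4 + 1) + b[co];
          op[base + (size_t)(2 * j + 1) * Ho + 2 * i]     = o(s, co * 4 + 2) + b[co];
          op[base + (size_t)(2 * j + 1) * Ho + 2 * i + 1] = o(s, co * 4 + 3) + b[co];
        }
  }
  return out;
}

// [[Rcpp::export]]
List upconv2_bw(NumericVector x, NumericVector w, NumericVector dy) {
  IntegerVector xd = x.attr("dim"), wd = w.attr("dim");
  int H = xd[0], W = xd[1], Cin = xd[2], N = xd[3], Cout = wd[3];
  int Ho = 2 * H, Wo = 2 * W;
  NumericVector dx((size_t)H * W * Cin * N);
  dx.attr("dim") = xd;
  arma::mat dWm(Cin, 4 * Cout, arma::fill::zeros);
  arma::vec db(Cout, arma::fill::zeros);
  arma::mat Wm(Cin, 4 * Cout);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          Wm(ci, co * 4 + dj * 2 + di) =
              w[(size_t)((co * Cin + ci) * 2 + dj) * 2 + di];
  arma::mat dyg(H * W, 4 * Cout);
  for (int n = 0; n < N; ++n) {
    const double* dyp = dy.begin() + (size_t)n * Ho * Wo * Cout;
    for (int co = 0; co < Cout; ++co) {
      size_t base = (size_t)co * Ho * Wo;
      double acc = 0.0;
      for (int j = 0; j < W; ++j)
        for (int i = 0; i < H; ++i) {
          size_t s = (size_t)j * H + i;
          double g00 = dyp[base + (size_t)(2 * j) * Ho + 2 * i];
          double g10 = dyp[base + (size_t)(2 * j) * Ho + 2 * i + 1];
          double g01 = dyp[base + (size_t)(2 * j + 1) * Ho + 2 * i];
          double g11 = dyp[base + (size_t)(2 * j + 1) * Ho + 2 * i + 1];
          dyg(s, co * 4 + 0) = g00; dyg(s, co * 4 + 1) = g10;
          dyg(s, co * 4 + 2) = g01; dyg(s, co * 4 + 3) = g11;
          acc += g00 + g10 + g01 + g11;
        }
      db(co) += acc;
    }
    arma::mat xm(const_cast<double*>(x.begin()) + (size_t)n * H * W * Cin,
                 H * W, Cin, false);
    dWm += xm.t() * dyg;
    arma::mat dxm = dyg * Wm.t();  // (H*W) x Cin
    double* dxp = dx.begin() + (size_t)n * H * W * Cin;
    std::copy(dxm.begin(), dxm.end(), dxp);
  }
  NumericVector dw(wd[0] * wd[1] * wd[2] * wd[3]);
  for (int co = 0; co < Cout; ++co)
    for (int ci = 0; ci < Cin; ++ci)
      for (int dj = 0; dj < 2; ++dj)
        for (int di = 0; di < 2; ++di)
          dw[(size_t)((co * Cin + ci) * 2 + dj) * 2 + di] =
              dWm(ci, co * 4 + dj * 2 + di);
  dw.attr("dim") = wd;
  return List::create(_["dx"] = dx, _["dw"] = dw,
                      _["db"] = NumericVector(db.begin(), db.end()));
}

// Connected-component labelling of a 3D logical array, 26- or 6-connectivity.
// Returns integer array of component labels (0 = background), labelled in
// raster-scan discovery order so label 1 starts at the lowest linear index.
// [[Rcpp::export]]
IntegerVector label_components3d(LogicalVector mask, IntegerVector dim,
                                 int connectivity = 26) {
  int X = dim[0], Y = dim[1], Z = dim[2];
  IntegerVector lab((size_t)X * Y * Z);
  lab.attr("dim") = dim;
  int next = 0;
  std::queue<int> q;
  for (int idx = 0; idx < X * Y * Z; ++idx) {
    if (!mask[idx] || lab[idx]) continue;
    lab[idx] = ++next;
    q.push(idx);
    while (!q.empty()) {
      int cur = q.front(); q.pop();
      int z = cur / (X * Y), r = cur % (X * Y), y = r / X, x = r % X;
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            if (connectivity == 6 && std::abs(dx) + std::abs(dy) + std::abs(dz) != 1)
              continue;
            int nx = x + dx, ny = y + dy, nz = z + dz;
            if (nx < 0 || nx >= X || ny < 0 || ny >= Y || nz < 0 || nz >= Z)
              continue;
            int ni = (nz * Y + ny) * X + nx;
            if (mask[ni] && !lab[ni]) { lab[ni] = next; q.push(ni); }
          }
    }
  }
  lab.attr("n_components") = next;
  return lab;
}
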