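// Compiled numerical core: convolutional network engine (im2col+GEMM
// convolutions, pooling, batch normalisation, dense layers, hand-derived
// backprop for the classifier CNN and the U-Net), bilinear projective
// warping, connected-component labelling, and the synthetic scene renderer.
//
// Batched feature maps are arma::cube(H, W, C*N): slice index s = c + C*n,
// memory-compatible with an R array of dim c(H, W, C, N).  All R-facing
// pixel coordinates are 1-based (row, col); internal loops are 0-based.

#include <RcppArmadillo.h>
#include <R_ext/BLAS.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::cube;
using arma::mat;
using arma::vec;

#ifndef FCONE
#define FCONE
#endif

static void dgemm_ld(char ta, char tb, int m, int n, int k, double alpha,
                     const double* A, int lda, const double* B, int ldb,
                     double beta, double* C, int ldc) {
  F77_CALL(dgemm)(&ta, &tb, &m, &n, &k, &alpha, A, &lda, B, &ldb,
                  &beta, C, &ldc FCONE FCONE);
}

// ---------------------------------------------------------------------------
// primitives
// ---------------------------------------------------------------------------

// Same-padding convolution, stride 1, odd kernel k, implemented as k*k
// shifted GEMMs over a zero-padded (Hp*Wp) x C plane matrix: for each kernel
// offset, the contribution to every output pixel is a single matrix product
// between a row-shifted view of the padded input and a (Cin x Cout) weight
// slice.  Rows outside the valid range hold padding garbage and are
// discarded when copying the interior back out.  This avoids im2col's large
// intermediate entirely; all heavy lifting is BLAS.
//
// Wm: (k*k*Cin) x Cout with row order kr + k*kc + k*k*ci, matching an R
// weight array of dim (k, k, Cin, Cout).

// per-offset weight slices Wk[kr + k*kc]: (Cin x Cout)
static std::vector<mat> weight_slices(const mat& Wm, int Cin, int Cout, int k) {
  std::vector<mat> Wk(k * k, mat(Cin, Cout));
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr) {
      mat& w = Wk[kr + k * kc];
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co)
          w(ci, co) = Wm(kr + k * kc + k * k * ci, co);
    }
  return Wk;
}

// copy sample n of X into a zero-padded (Hp*Wp) x Cin plane matrix
static void pad_planes(const cube& X, int n, int Cin, int p, mat& Xp) {
  const int H = X.n_rows, W = X.n_cols, Hp = H + 2 * p;
  Xp.zeros();
  for (int ci = 0; ci < Cin; ++ci) {
    const mat& S = X.slice((size_t)n * Cin + ci);
    double* dst = Xp.colptr(ci);
    for (int c = 0; c < W; ++c)
      std::copy(S.colptr(c), S.colptr(c) + H, dst + (size_t)Hp * (c + p) + p);
  }
}

static cube conv_fwd(const cube& X, const mat& Wm, const vec& b,
                     int N, int Cin, int Cout, int k) {
  const int H = X.n_rows, W = X.n_cols, p = (k - 1) / 2;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t P = (size_t)Hp * Wp;
  cube Y(H, W, (size_t)Cout * N);
  mat Xp(P, Cin), Yf(P, Cout);
  std::vector<mat> Wk = weight_slices(Wm, Cin, Cout, k);
  for (int n = 0; n < N; ++n) {
    pad_planes(X, n, Cin, p, Xp);
    Yf.zeros();
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int s = (kr - p) + Hp * (kc - p);
        const int a = std::max(0, -s);
        const int len = (int)P - std::abs(s);
        dgemm_ld('N', 'N', len, Cout, Cin, 1.0, Xp.memptr() + a + s, (int)P,
                 Wk[kr + k * kc].memptr(), Cin, 1.0, Yf.memptr() + a, (int)P);
      }
    for (int co = 0; co < Cout; ++co) {
      mat& out = Y.slice((size_t)n * Cout + co);
      const double* src = Yf.colptr(co);
      const double bias = b(co);
      for (int c = 0; c < W; ++c) {
        const double* sp = src + (size_t)Hp * (c + p) + p;
        double* dp = out.colptr(c);
        for (int r = 0; r < H; ++r) dp[r] = sp[r] + bias;
      }
    }
  }
  return Y;
}

static void conv_bwd(const cube& X, const cube& dY, const mat& Wm,
                     int N, int Cin, int Cout, int k,
                     cube& dX, mat& dW, vec& db, bool want_dx) {
  const int H = X.n_rows, W = X.n_cols, p = (k - 1) / 2;
  const int Hp = H + 2 * p, Wp = W + 2 * p;
  const size_t P = (size_t)Hp * Wp;
  dW.zeros(k * k * Cin, Cout);
  db.zeros(Cout);
  if (want_dx) dX.set_size(H, W, (size_t)Cin * N);
  std::vector<mat> Wk = weight_slices(Wm, Cin, Cout, k);
  std::vector<mat> dWk(k * k, mat(Cin, Cout, arma::fill::zeros));
  mat Xp(P, Cin), dYf(P, Cout), dXp(P, Cin);
  for (int n = 0; n < N; ++n) {
    pad_planes(X, n, Cin, p, Xp);
    pad_planes(dY, n, Cout, p, dYf);
    for (int co = 0; co < Cout; ++co)
      db(co) += arma::accu(dY.slice((size_t)n * Cout + co));
    if (want_dx) dXp.zeros();
    for (int kc = 0; kc < k; ++kc)
      for (int kr = 0; kr < k; ++kr) {
        const int s = (kr - p) + Hp * (kc - p);
        const int a = std::max(0, -s);
        const int len = (int)P - std::abs(s);
        // dW_k += Xp_shifted^T dY ; dXp_shifted += dY Wk^T
        dgemm_ld('T', 'N', Cin, Cout, len, 1.0, Xp.memptr() + a + s, (int)P,
                 dYf.memptr() + a, (int)P, 1.0, dWk[kr + k * kc].memptr(), Cin);
        if (want_dx)
          dgemm_ld('N', 'T', len, Cin, Cout, 1.0, dYf.memptr() + a, (int)P,
                   Wk[kr + k * kc].memptr(), Cin, 1.0, dXp.memptr() + a + s, (int)P);
      }
    if (want_dx)
      for (int ci = 0; ci < Cin; ++ci) {
        mat& out = dX.slice((size_t)n * Cin + ci);
        const double* src = dXp.colptr(ci);
        for (int c = 0; c < W; ++c)
          std::copy(src + (size_t)Hp * (c + p) + p,
                    src + (size_t)Hp * (c + p) + p + H, out.colptr(c));
      }
  }
  for (int kc = 0; kc < k; ++kc)
    for (int kr = 0; kr < k; ++kr)
      for (int ci = 0; ci < Cin; ++ci)
        for (int co = 0; co < Cout; ++co)
          dW(kr + k * kc + k * k * ci, co) = dWk[kr + k * kc](ci, co);
}

// leaky ReLU in place; backward derives the mask from the output sign
static void leaky_fwd(cube& X, double slope) {
  X.transform([slope](double v) { return v > 0 ? v : slope * v; });
}
static void leaky_bwd(const cube& Y, cube& dY, double slope) {
  const size_t n = Y.n_elem;
  const double* y = Y.memptr();
  double* g = dY.memptr();
  for (size_t i = 0; i < n; ++i) if (y[i] <= 0) g[i] *= slope;
}

static inline int pool_out(int n, int k, int s) { return (n - k) / s + 1; }

// average pooling, kernel k, stride s, no padding
static cube avgpool_fwd(const cube& X, int k, int s) {
  const int H = X.n_rows, W = X.n_cols, S = X.n_slices;
  const int Ho = pool_out(H, k, s), Wo = pool_out(W, k, s);
  cube Y(Ho, Wo, S);
  const double inv = 1.0 / (k * k);
  for (int sl = 0; sl < S; ++sl) {
    const mat& A = X.slice(sl);
    mat& B = Y.slice(sl);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        B(r, c) = inv * arma::accu(A.submat(r * s, c * s, r * s + k - 1, c * s + k - 1));
  }
  return Y;
}
static cube avgpool_bwd(const cube& dY, int H, int W, int k, int s) {
  const int S = dY.n_slices, Ho = dY.n_rows, Wo = dY.n_cols;
  cube dX(H, W, S, arma::fill::zeros);
  const double inv = 1.0 / (k * k);
  for (int sl = 0; sl < S; ++sl) {
    const mat& G = dY.slice(sl);
    mat& D = dX.slice(sl);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        D.submat(r * s, c * s, r * s + k - 1, c * s + k - 1) += inv * G(r, c);
  }
  return dX;
}

// 2x2 max pooling, stride 2 (inputs padded to even size by the caller)
static cube maxpool2_fwd(const cube& X, arma::umat& argmax) {
  const int H = X.n_rows, W = X.n_cols, S = X.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  cube Y(Ho, Wo, S);
  argmax.set_size((size_t)Ho * Wo, S);
  for (int sl = 0; sl < S; ++sl) {
    const mat& A = X.slice(sl);
    mat& B = Y.slice(sl);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r) {
        double best = A(2 * r, 2 * c);
        arma::uword bi = (size_t)H * (2 * c) + 2 * r;
        const int rr[4] = {2 * r + 1, 2 * r, 2 * r + 1, 2 * r};
        const int cc[4] = {2 * c, 2 * c + 1, 2 * c + 1, 2 * c};
        for (int j = 0; j < 3; ++j) {
          double v = A(rr[j], cc[j]);
          if (v > best) { best = v; bi = (size_t)H * cc[j] + rr[j]; }
        }
        B(r, c) = best;
        argmax((size_t)Ho * c + r, sl) = bi;
      }
  }
  return Y;
}
static cube maxpool2_bwd(const cube& dY, const arma::umat& argmax, int H, int W) {
  const int S = dY.n_slices;
  cube dX(H, W, S, arma::fill::zeros);
  for (int sl = 0; sl < S; ++sl) {
    const double* g = dY.slice(sl).memptr();
    double* d = dX.slice(sl).memptr();
    const arma::uword* am = argmax.colptr(sl);
    const size_t n = dY.n_rows * dY.n_cols;
    for (size_t i = 0; i < n; ++i) d[am[i]] += g[i];
  }
  return dX;
}

// nearest-neighbour x2 upsampling
static cube upsample2_fwd(const cube& X) {
  const int H = X.n_rows, W = X.n_cols, S = X.n_slices;
  cube Y(2 * H, 2 * W, S);
  for (int sl = 0; sl < S; ++sl) {
    const mat& A = X.slice(sl);
    mat& B = Y.slice(sl);
    for (int c = 0; c < W; ++c)
      for (int r = 0; r < H; ++r) {
        const double v = A(r, c);
        B(2 * r, 2 * c) = v; B(2 * r + 1, 2 * c) = v;
        B(2 * r, 2 * c + 1) = v; B(2 * r + 1, 2 * c + 1) = v;
      }
  }
  return Y;
}
static cube upsample2_bwd(const cube& dY) {
  const int Ho = dY.n_rows / 2, Wo = dY.n_cols / 2, S = dY.n_slices;
  cube dX(Ho, Wo, S);
  for (int sl = 0; sl < S; ++sl) {
    const mat& G = dY.slice(sl);
    mat& D = dX.slice(sl);
    for (int c = 0; c < Wo; ++c)
      for (int r = 0; r < Ho; ++r)
        D(r, c) = G(2 * r, 2 * c) + G(2 * r + 1, 2 * c) +
                  G(2 * r, 2 * c + 1) + G(2 * r + 1, 2 * c + 1);
  }
  return dX;
}

// channel concatenation [A | B] per sample
static cube concat_ch(const cube& A, const cube& B, int N, int Ca, int Cb) {
  cube Y(A.n_rows, A.n_cols, (size_t)(Ca + Cb) * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Ca; ++c) Y.slice((size_t)n * (Ca + Cb) + c) = A.slice((size_t)n * Ca + c);
    for (int c = 0; c < Cb; ++c) Y.slice((size_t)n * (Ca + Cb) + Ca + c) = B.slice((size_t)n * Cb + c);
  }
  return Y;
}
static void split_ch(const cube& dY, int N, int Ca, int Cb, cube& dA, cube& dB) {
  dA.set_size(dY.n_rows, dY.n_cols, (size_t)Ca * N);
  dB.set_size(dY.n_rows, dY.n_cols, (size_t)Cb * N);
  for (int n = 0; n < N; ++n) {
    for (int c = 0; c < Ca; ++c) dA.slice((size_t)n * Ca + c) = dY.slice((size_t)n * (Ca + Cb) + c);
    for (int c = 0; c < Cb; ++c) dB.slice((size_t)n * Cb + c) = dY.slice((size_t)n * (Ca + Cb) + Ca + c);
  }
}

// batch normalisation over (N, H, W) per channel
struct BNCache { vec mean, invstd; };

static void bn_fwd_train(cube& X, int N, int C, const vec& gamma, const vec& beta,
                         vec& rmean, vec& rvar, double momentum, double eps,
                         BNCache& cache) {
  const size_t hw = (size_t)X.n_rows * X.n_cols;
  const double m = (double)N * hw;
  cache.mean.set_size(C); cache.invstd.set_size(C);
  for (int c = 0; c < C; ++c) {
    double s = 0, ss = 0;
    for (int n = 0; n < N; ++n) {
      const double* p = X.slice((size_t)n * C + c).memptr();
      for (size_t i = 0; i < hw; ++i) { s += p[i]; ss += p[i] * p[i]; }
    }
    const double mu = s / m;
    const double var = std::max(ss / m - mu * mu, 0.0);
    const double is = 1.0 / std::sqrt(var + eps);
    cache.mean(c) = mu; cache.invstd(c) = is;
    rmean(c) = momentum * rmean(c) + (1 - momentum) * mu;
    rvar(c) = momentum * rvar(c) + (1 - momentum) * var;
    const double a = gamma(c) * is, b = beta(c) - gamma(c) * is * mu;
    for (int n = 0; n < N; ++n) {
      double* p = X.slice((size_t)n * C + c).memptr();
      for (size_t i = 0; i < hw; ++i) p[i] = a * p[i] + b;
    }
  }
}

static void bn_fwd_eval(cube& X, int N, int C, const vec& gamma, const vec& beta,
                        const vec& rmean, const vec& rvar, double eps) {
  const size_t hw = (size_t)X.n_rows * X.n_cols;
  for (int c = 0; c < C; ++c) {
    const double is = 1.0 / std::sqrt(rvar(c) + eps);
    const double a = gamma(c) * is, b = beta(c) - gamma(c) * is * rmean(c);
    for (int n = 0; n < N; ++n) {
      double* p = X.slice((size_t)n * C + c).memptr();
      for (size_t i = 0; i < hw; ++i) p[i] = a * p[i] + b;
    }
  }
}

// X here is the *input* saved before bn_fwd_train overwrote it
static void bn_bwd(const cube& Xin, cube& dY, int N, int C,
                   const vec& gamma, const BNCache& cache,
                   vec& dgamma, vec& dbeta) {
  const size_t hw = (size_t)Xin.n_rows * Xin.n_cols;
  const double m = (double)N * hw;
  dgamma.zeros(C); dbeta.zeros(C);
  for (int c = 0; c < C; ++c) {
    const double mu = cache.mean(c), is = cache.invstd(c);
    double sdy = 0, sdyx = 0;
    for (int n = 0; n < N; ++n) {
      const double* x = Xin.slice((size_t)n * C + c).memptr();
      const double* g = dY.slice((size_t)n * C + c).memptr();
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (x[i] - mu) * is;
        sdy += g[i]; sdyx += g[i] * xh;
      }
    }
    dgamma(c) = sdyx; dbeta(c) = sdy;
    const double k = gamma(c) * is / m;
    for (int n = 0; n < N; ++n) {
      const double* x = Xin.slice((size_t)n * C + c).memptr();
      double* g = dY.slice((size_t)n * C + c).memptr();
      for (size_t i = 0; i < hw; ++i) {
        const double xh = (x[i] - mu) * is;
        g[i] = k * (m * g[i] - sdy - xh * sdyx);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// helpers bridging R arrays and cubes
// ---------------------------------------------------------------------------

static cube as_batch(const NumericVector& x, int& H, int& W, int& C, int& N) {
  IntegerVector d = x.attr("dim");
  H = d[0]; W = d[1];
  C = d.size() > 2 ? d[2] : 1;
  N = d.size() > 3 ? d[3] : 1;
  cube X(const_cast<double*>(x.begin()), H, W, (size_t)C * N, true);
  return X;
}

static NumericVector cube_to_r(const cube& X, int C, int N) {
  NumericVector out(X.n_elem);
  std::copy(X.memptr(), X.memptr() + X.n_elem, out.begin());
  out.attr("dim") = IntegerVector::create(X.n_rows, X.n_cols, C, N);
  return out;
}

static mat list_mat(const List& L, const char* nm) {
  NumericVector v = L[nm];
  IntegerVector d = v.attr("dim");
  int nr, nc;
  if (d.size() == 2) { nr = d[0]; nc = d[1]; }
  else if (d.size() == 4) { nr = d[0] * d[1] * d[2]; nc = d[3]; }  // conv weights
  else { nr = v.size(); nc = 1; }
  return mat(v.begin(), nr, nc, true);
}
static vec list_vec(const List& L, const char* nm) {
  NumericVector v = L[nm];
  return vec(v.begin(), v.size(), true);
}
static NumericVector wrap_like(const mat& g, SEXP proto) {
  NumericVector out(g.n_elem);
  std::copy(g.memptr(), g.memptr() + g.n_elem, out.begin());
  out.attr("dim") = Rf_getAttrib(proto, R_DimSymbol);
  return out;
}

// ---------------------------------------------------------------------------
// classifier CNN: conv trunk per plan -> BN -> LeakyReLU -> optional avgpool;
// flatten + attributes -> dense(hidden) -> LeakyReLU -> dropout -> dense(n_out)
// ---------------------------------------------------------------------------

struct CnnTrace {
  std::vector<cube> conv_in;    // input to each conv
  std::vector<cube> bn_in;      // conv output before BN (needed by bn_bwd)
  std::vector<cube> act_out;    // after activation (pre-pool)
  std::vector<arma::imat> dims; // unused
  std::vector<BNCache> bn;
  std::vector<int> Hpre, Wpre;  // spatial size before pooling at each layer
  mat feat;                     // (F+A) x N features into fc1
  mat h1;                       // hidden after activation+dropout
};

static std::string pname(const char* base, int i) {
  char buf[32];
  snprintf(buf, sizeof(buf), "%s%d", base, i + 1);
  return std::string(buf);
}

// forward through the conv trunk; training switches BN mode
static cube cnn_trunk(cube X, const List& params, List& state, const List& arch,
                      int N, bool training, CnnTrace* tr) {
  IntegerVector channels = arch["channels"];
  LogicalVector pool = arch["pool"];
  const int L = channels.size();
  const double slope = as<double>(arch["slope"]);
  const double eps = as<double>(arch["bn_eps"]);
  const double mom = as<double>(arch["bn_momentum"]);
  const int pk = as<int>(arch["pool_kernel"]);
  const int ps = as<int>(arch["pool_stride"]);
  int Cin = as<int>(arch["in_ch"]);
  for (int l = 0; l < L; ++l) {
    const int Cout = channels[l];
    mat Wm = list_mat(params, pname("cw", l).c_str());
    vec b = list_vec(params, pname("cb", l).c_str());
    if (tr) tr->conv_in.push_back(X);
    cube Y = conv_fwd(X, Wm, b, N, Cin, Cout, 3);
    vec gamma = list_vec(params, pname("bng", l).c_str());
    vec beta = list_vec(params, pname("bnb", l).c_str());
    if (training) {
      vec rm = list_vec(state, pname("bnm", l).c_str());
      vec rv = list_vec(state, pname("bnv", l).c_str());
      BNCache bc;
      if (tr) tr->bn_in.push_back(Y);
      bn_fwd_train(Y, N, Cout, gamma, beta, rm, rv, mom, eps, bc);
      if (tr) tr->bn.push_back(bc);
      state[pname("bnm", l)] = NumericVector(rm.begin(), rm.end());
      state[pname("bnv", l)] = NumericVector(rv.begin(), rv.end());
    } else {
      vec rm = list_vec(state, pname("bnm", l).c_str());
      vec rv = list_vec(state, pname("bnv", l).c_str());
      bn_fwd_eval(Y, N, Cout, gamma, beta, rm, rv, eps);
    }
    leaky_fwd(Y, slope);
    if (tr) { tr->act_out.push_back(Y); tr->Hpre.push_back(Y.n_rows); tr->Wpre.push_back(Y.n_cols); }
    if (pool[l]) Y = avgpool_fwd(Y, pk, ps);
    X = Y;
    Cin = Cout;
  }
  return X;
}

static mat flatten_with_attrs(const cube& X, const mat& attrs, int C, int N) {
  const size_t hw = (size_t)X.n_rows * X.n_cols;
  const int F = (int)(hw * C);
  const int A = attrs.n_rows;
  mat feat(F + A, N);
  for (int n = 0; n < N; ++n) {
    double* col = feat.colptr(n);
    for (int c = 0; c < C; ++c) {
      const double* p = X.slice((size_t)n * C + c).memptr();
      std::copy(p, p + hw, col + (size_t)c * hw);
    }
    for (int a = 0; a < A; ++a) col[F + a] = attrs(a, n);
  }
  return feat;
}

// [[Rcpp::export]]
List cpp_cnn_forward(NumericVector x, NumericMatrix attrs, List params, List state,
                     List arch, bool training, Nullable<NumericMatrix> dropout_mask) {
  int H, W, C, N;
  cube X = as_batch(x, H, W, C, N);
  mat At(attrs.begin(), attrs.nrow(), attrs.ncol(), true);
  const double slope = as<double>(arch["slope"]);
  IntegerVector channels = arch["channels"];
  const int Cl = channels[channels.size() - 1];
  cube T = cnn_trunk(X, params, state, arch, N, training, nullptr);
  mat feat = flatten_with_attrs(T, At, Cl, N);
  mat W1 = list_mat(params, "fw1"), W2 = list_mat(params, "fw2");
  vec b1 = list_vec(params, "fb1"), b2 = list_vec(params, "fb2");
  mat h = W1 * feat;
  h.each_col() += b1;
  h.transform([slope](double v) { return v > 0 ? v : slope * v; });
  if (training && dropout_mask.isNotNull()) {
    NumericMatrix dm(dropout_mask);
    h %= mat(dm.begin(), dm.nrow(), dm.ncol(), false);
  }
  mat z = W2 * h;
  z.each_col() += b2;
  return List::create(_["logits"] = wrap(z), _["state"] = state);
}

// combined forward + loss + backward (training step)
// y: 0/1 labels length N; n_out 1 (sigmoid BCE) or 2 (softmax CE)
// [[Rcpp::export]]
List cpp_cnn_fwdbwd(NumericVector x, NumericMatrix attrs, NumericVector y,
                    List params, List state, List arch, NumericMatrix dropout_mask) {
  int H, W, C, N;
  cube X = as_batch(x, H, W, C, N);
  mat At(attrs.begin(), attrs.nrow(), attrs.ncol(), true);
  IntegerVector channels = arch["channels"];
  LogicalVector pool = arch["pool"];
  const int L = channels.size();
  const int Cl = channels[L - 1];
  const double slope = as<double>(arch["slope"]);
  const int pk = as<int>(arch["pool_kernel"]);
  const int ps = as<int>(arch["pool_stride"]);
  const int n_out = as<int>(arch["n_out"]);

  CnnTrace tr;
  cube T = cnn_trunk(X, params, state, arch, N, true, &tr);
  tr.feat = flatten_with_attrs(T, At, Cl, N);

  mat W1 = list_mat(params, "fw1"), W2 = list_mat(params, "fw2");
  vec b1 = list_vec(params, "fb1"), b2 = list_vec(params, "fb2");
  mat h = W1 * tr.feat;
  h.each_col() += b1;
  mat hpre = h;
  h.transform([slope](double v) { return v > 0 ? v : slope * v; });
  mat dmask(dropout_mask.begin(), dropout_mask.nrow(), dropout_mask.ncol(), true);
  h %= dmask;
  tr.h1 = h;
  mat z = W2 * h;
  z.each_col() += b2;

  // loss and dlogits
  double loss = 0;
  mat dz(z.n_rows, N);
  vec probs(N);
  if (n_out == 1) {
    for (int n = 0; n < N; ++n) {
      const double zz = z(0, n), yy = y[n];
      loss += std::max(zz, 0.0) - zz * yy + std::log1p(std::exp(-std::fabs(zz)));
      const double p = 1.0 / (1.0 + std::exp(-zz));
      probs(n) = p;
      dz(0, n) = (p - yy) / N;
    }
  } else {
    for (int n = 0; n < N; ++n) {
      const double m = std::max(z(0, n), z(1, n));
      const double lse = m + std::log(std::exp(z(0, n) - m) + std::exp(z(1, n) - m));
      const double yy = y[n];
      loss += lse - (yy > 0.5 ? z(1, n) : z(0, n));
      const double p1 = std::exp(z(1, n) - lse);
      probs(n) = p1;
      dz(0, n) = ((1 - p1) - (yy > 0.5 ? 0.0 : 1.0)) / N;
      dz(1, n) = (p1 - (yy > 0.5 ? 1.0 : 0.0)) / N;
    }
  }
  loss /= N;

  List grads;
  // head backward
  mat dW2 = dz * tr.h1.t();
  vec db2 = arma::sum(dz, 1);
  mat dh = W2.t() * dz;
  dh %= dmask;
  for (size_t i = 0; i < dh.n_elem; ++i) if (hpre(i) <= 0) dh(i) *= slope;
  mat dW1 = dh * tr.feat.t();
  vec db1 = arma::sum(dh, 1);
  mat dfeat = W1.t() * dh;
  grads["fw2"] = wrap_like(dW2, params["fw2"]);
  grads["fb2"] = NumericVector(db2.begin(), db2.end());
  grads["fw1"] = wrap_like(dW1, params["fw1"]);
  grads["fb1"] = NumericVector(db1.begin(), db1.end());

  // unflatten (attribute gradients are discarded: attributes are inputs)
  const size_t hw = (size_t)T.n_rows * T.n_cols;
  cube dT(T.n_rows, T.n_cols, (size_t)Cl * N);
  for (int n = 0; n < N; ++n) {
    const double* col = dfeat.colptr(n);
    for (int c = 0; c < Cl; ++c) {
      double* p = dT.slice((size_t)n * Cl + c).memptr();
      std::copy(col + (size_t)c * hw, col + (size_t)(c + 1) * hw, p);
    }
  }

  // trunk backward
  cube dcur = dT;
  for (int l = L - 1; l >= 0; --l) {
    const int Cout = channels[l];
    const int Cin = l == 0 ? as<int>(arch["in_ch"]) : (int)channels[l - 1];
    if (pool[l]) dcur = avgpool_bwd(dcur, tr.Hpre[l], tr.Wpre[l], pk, ps);
    leaky_bwd(tr.act_out[l], dcur, slope);
    vec gamma = list_vec(params, pname("bng", l).c_str());
    vec dgamma, dbeta;
    bn_bwd(tr.bn_in[l], dcur, N, Cout, gamma, tr.bn[l], dgamma, dbeta);
    grads[pname("bng", l)] = NumericVector(dgamma.begin(), dgamma.end());
    grads[pname("bnb", l)] = NumericVector(dbeta.begin(), dbeta.end());
    mat Wm = list_mat(params, pname("cw", l).c_str());
    cube dXl; mat dW; vec db;
    conv_bwd(tr.conv_in[l], dcur, Wm, N, Cin, Cout, 3, dXl, dW, db, l > 0);
    grads[pname("cw", l)] = wrap_like(dW, params[pname("cw", l)]);
    grads[pname("cb", l)] = NumericVector(db.begin(), db.end());
    if (l > 0) dcur = dXl;
  }

  return List::create(_["loss"] = loss,
                      _["probs"] = NumericVector(probs.begin(), probs.end()),
                      _["grads"] = grads, _["state"] = state);
}

// ---------------------------------------------------------------------------
// U-Net: encoder (2 convs + ReLU per level, 2x2 maxpool), bottleneck,
// decoder (x2 nearest upsample + conv, skip concat, 2 convs), 1x1 sigmoid head.
// No batch norm (original recipe).  Input sizes must be multiples of 2^depth.
// ---------------------------------------------------------------------------

struct UnetDims { int depth; std::vector<int> w; int in_ch; };

static UnetDims unet_dims(const List& arch) {
  UnetDims d;
  d.depth = as<int>(arch["depth"]);
  IntegerVector w = arch["widths"];  // length depth+1
  d.w.assign(w.begin(), w.end());
  d.in_ch = as<int>(arch["in_ch"]);
  return d;
}

struct UnetTrace {
  std::vector<cube> enc_in1, enc_in2, enc_out1, enc_out2; // per level conv inputs/outputs
  std::vector<arma::umat> pool_arg;
  std::vector<int> pool_h, pool_w;
  cube bott_in1, bott_in2, bott_out1, bott_out2;
  std::vector<cube> up_in, upconv_out, cat, dec_in2, dec_out1, dec_out2;
  cube head_in;
};

static cube conv_relu(const cube& X, const List& params, const char* nm,
                      int N, int Cin, int Cout, int k, cube* save_in, cube* save_out) {
  mat Wm = list_mat(params, nm);
  std::string bn(nm); bn[0] = 'b';  // "wxxx" -> "bxxx"
  vec b = list_vec(params, bn.c_str());
  if (save_in) *save_in = X;
  cube Y = conv_fwd(X, Wm, b, N, Cin, Cout, k);
  leaky_fwd(Y, 0.0);
  if (save_out) *save_out = Y;
  return Y;
}

static cube unet_forward(const cube& X0, const List& params, const UnetDims& d,
                         int N, UnetTrace* tr) {
  const int D = d.depth;
  std::vector<cube> skips(D);
  cube X = X0;
  int Cin = d.in_ch;
  if (tr) {
    tr->enc_in1.resize(D); tr->enc_in2.resize(D); tr->enc_out1.resize(D); tr->enc_out2.resize(D);
    tr->pool_arg.resize(D); tr->pool_h.resize(D); tr->pool_w.resize(D);
    tr->up_in.resize(D); tr->upconv_out.resize(D); tr->cat.resize(D);
    tr->dec_in2.resize(D); tr->dec_out1.resize(D); tr->dec_out2.resize(D);
  }
  for (int l = 0; l < D; ++l) {
    X = conv_relu(X, params, pname("we", 2 * l).c_str(), N, Cin, d.w[l], 3,
                  tr ? &tr->enc_in1[l] : nullptr, tr ? &tr->enc_out1[l] : nullptr);
    X = conv_relu(X, params, pname("we", 2 * l + 1).c_str(), N, d.w[l], d.w[l], 3,
                  tr ? &tr->enc_in2[l] : nullptr, tr ? &tr->enc_out2[l] : nullptr);
    skips[l] = X;
    arma::umat am;
    if (tr) { tr->pool_h[l] = X.n_rows; tr->pool_w[l] = X.n_cols; }
    X = maxpool2_fwd(X, am);
    if (tr) tr->pool_arg[l] = am;
    Cin = d.w[l];
  }
  X = conv_relu(X, params, "wb1", N, d.w[D - 1], d.w[D], 3,
                tr ? &tr->bott_in1 : nullptr, tr ? &tr->bott_out1 : nullptr);
  X = conv_relu(X, params, "wb2", N, d.w[D], d.w[D], 3,
                tr ? &tr->bott_in2 : nullptr, tr ? &tr->bott_out2 : nullptr);
  for (int l = D - 1; l >= 0; --l) {
    const int Cup = l == D - 1 ? d.w[D] : d.w[l + 1];
    if (tr) tr->up_in[l] = X;
    cube U = upsample2_fwd(X);
    U = conv_relu(U, params, pname("wu", l).c_str(), N, Cup, d.w[l], 3,
                  nullptr, tr ? &tr->upconv_out[l] : nullptr);
    cube Ccat = concat_ch(skips[l], U, N, d.w[l], d.w[l]);
    if (tr) tr->cat[l] = Ccat;
    cube Y = conv_relu(Ccat, params, pname("wd", 2 * l).c_str(), N, 2 * d.w[l], d.w[l], 3,
                       nullptr, tr ? &tr->dec_out1[l] : nullptr);
    if (tr) tr->dec_in2[l] = Y;
    X = conv_relu(Y, params, pname("wd", 2 * l + 1).c_str(), N, d.w[l], d.w[l], 3,
                  nullptr, tr ? &tr->dec_out2[l] : nullptr);
  }
  if (tr) tr->head_in = X;
  mat Wm = list_mat(params, "wo");
  vec b = list_vec(params, "bo");
  return conv_fwd(X, Wm, b, N, d.w[0], 1, 1);  // logits
}

// [[Rcpp::export]]
NumericVector cpp_unet_predict(NumericVector x, List params, List arch) {
  int H, W, C, N;
  cube X = as_batch(x, H, W, C, N);
  UnetDims d = unet_dims(arch);
  cube Z = unet_forward(X, params, d, N, nullptr);
  Z.transform([](double z) { return 1.0 / (1.0 + std::exp(-z)); });
  return cube_to_r(Z, 1, N);
}

// gradient of a conv+relu block given upstream dY; returns dX, stores grads
static cube conv_relu_bwd(const cube& Xin, const cube& Yout, cube dY,
                          const List& params, List& grads, const char* nm,
                          int N, int Cin, int Cout, int k, bool want_dx) {
  leaky_bwd(Yout, dY, 0.0);
  mat Wm = list_mat(params, nm);
  cube dX; mat dW; vec db;
  conv_bwd(Xin, dY, Wm, N, Cin, Cout, k, dX, dW, db, want_dx);
  std::string bn(nm); bn[0] = 'b';
  grads[nm] = wrap_like(dW, params[nm]);
  grads[bn] = NumericVector(db.begin(), db.end());
  return dX;
}

// [[Rcpp::export]]
List cpp_unet_fwdbwd(NumericVector x, NumericVector ymask, List params, List arch) {
  int H, W, C, N;
  cube X = as_batch(x, H, W, C, N);
  int H2, W2, C2, N2;
  cube Y = as_batch(ymask, H2, W2, C2, N2);
  UnetDims d = unet_dims(arch);
  const int D = d.depth;
  UnetTrace tr;
  cube Z = unet_forward(X, params, d, N, &tr);

  // pixel-mean BCE with logits
  const double m = (double)Z.n_elem;
  double loss = 0;
  cube dZ(Z.n_rows, Z.n_cols, Z.n_slices);
  {
    const double* z = Z.memptr();
    const double* y = Y.memptr();
    double* g = dZ.memptr();
    for (size_t i = 0; i < Z.n_elem; ++i) {
      loss += std::max(z[i], 0.0) - z[i] * y[i] + std::log1p(std::exp(-std::fabs(z[i])));
      g[i] = (1.0 / (1.0 + std::exp(-z[i])) - y[i]) / m;
    }
    loss /= m;
  }

  List grads;
  // head (1x1 conv)
  mat Wo = list_mat(params, "wo");
  cube dX1; mat dWo; vec dbo;
  conv_bwd(tr.head_in, dZ, Wo, N, d.w[0], 1, 1, dX1, dWo, dbo, true);
  grads["wo"] = wrap_like(dWo, params["wo"]);
  grads["bo"] = NumericVector(dbo.begin(), dbo.end());

  cube dcur = dX1;
  for (int l = 0; l < D; ++l) {
    const int Cup = l == D - 1 ? d.w[D] : d.w[l + 1];
    dcur = conv_relu_bwd(tr.dec_in2[l], tr.dec_out2[l], dcur, params, grads,
                         pname("wd", 2 * l + 1).c_str(), N, d.w[l], d.w[l], 3, true);
    dcur = conv_relu_bwd(tr.cat[l], tr.dec_out1[l], dcur, params, grads,
                         pname("wd", 2 * l).c_str(), N, 2 * d.w[l], d.w[l], 3, true);
    cube dskip, dU;
    split_ch(dcur, N, d.w[l], d.w[l], dskip, dU);
    cube dUp = conv_relu_bwd(upsample2_fwd(tr.up_in[l]), tr.upconv_out[l], dU, params, grads,
                             pname("wu", l).c_str(), N, Cup, d.w[l], 3, true);
    cube dnext = upsample2_bwd(dUp);
    // dskip flows into the encoder at level l; dnext continues to level l+1
    // store dskip until the encoder pass; accumulate with pooled gradient there
    tr.cat[l] = dskip;  // reuse slot to carry the skip gradient
    dcur = dnext;
  }
  // dcur now is the gradient entering the bottleneck output path (level D)
  dcur = conv_relu_bwd(tr.bott_in2, tr.bott_out2, dcur, params, grads, "wb2",
                       N, d.w[D], d.w[D], 3, true);
  dcur = conv_relu_bwd(tr.bott_in1, tr.bott_out1, dcur, params, grads, "wb1",
                       N, d.w[D - 1], d.w[D], 3, true);
  for (int l = D - 1; l >= 0; --l) {
    const int Cin = l == 0 ? d.in_ch : d.w[l - 1];
    cube dpool = maxpool2_bwd(dcur, tr.pool_arg[l], tr.pool_h[l], tr.pool_w[l]);
    dpool += tr.cat[l];  // skip-connection gradient
    dcur = conv_relu_bwd(tr.enc_in2[l], tr.enc_out2[l], dpool, params, grads,
                         pname("we", 2 * l + 1).c_str(), N, d.w[l], d.w[l], 3, true);
    dcur = conv_relu_bwd(tr.enc_in1[l], tr.enc_out1[l], dcur, params, grads,
                         pname("we", 2 * l).c_str(), N, Cin, d.w[l], 3, l > 0);
  }

  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// ---------------------------------------------------------------------------
// bilinear projective warp: M maps output (r, c, 1) -> source (r, c, w),
// 1-based pixel-centre coordinates.  Outside pixels -> 0 with valid = FALSE.
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List cpp_warp_projective(NumericMatrix src, NumericMatrix M, int out_h, int out_w) {
  const int H = src.nrow(), W = src.ncol();
  NumericMatrix out(out_h, out_w);
  LogicalMatrix valid(out_h, out_w);
  const double m11 = M(0, 0), m12 = M(0, 1), m13 = M(0, 2);
  const double m21 = M(1, 0), m22 = M(1, 1), m23 = M(1, 2);
  const double m31 = M(2, 0), m32 = M(2, 1), m33 = M(2, 2);
  for (int c = 0; c < out_w; ++c) {
    const double cc = c + 1;
    for (int r = 0; r < out_h; ++r) {
      const double rr = r + 1;
      const double w = m31 * rr + m32 * cc + m33;
      if (std::fabs(w) < 1e-12) continue;
      const double rs = (m11 * rr + m12 * cc + m13) / w;
      const double cs = (m21 * rr + m22 * cc + m23) / w;
      if (rs < 1 || rs > H || cs < 1 || cs > W) continue;
      int r0 = (int)std::floor(rs), c0 = (int)std::floor(cs);
      if (r0 == H) r0 = H - 1;
      if (c0 == W) c0 = W - 1;
      const double fr = rs - r0, fc = cs - c0;
      const double v00 = src(r0 - 1, c0 - 1), v10 = src(r0, c0 - 1);
      const double v01 = src(r0 - 1, c0), v11 = src(r0, c0);
      out(r, c) = (1 - fr) * (1 - fc) * v00 + fr * (1 - fc) * v10 +
                  (1 - fr) * fc * v01 + fr * fc * v11;
      valid(r, c) = true;
    }
  }
  return List::create(_["pixels"] = out, _["valid"] = valid);
}

// ---------------------------------------------------------------------------
// 4-connected component labelling of a binary matrix
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
IntegerMatrix cpp_label_components(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  std::vector<int> stack;
  int next = 0;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (!mask(r, c) || lab(r, c)) continue;
      ++next;
      stack.push_back(r + H * c);
      lab(r, c) = next;
      while (!stack.empty()) {
        const int idx = stack.back(); stack.pop_back();
        const int cr = idx % H, cc = idx / H;
        const int nr[4] = {cr - 1, cr + 1, cr, cr};
        const int nc[4] = {cc, cc, cc - 1, cc + 1};
        for (int j = 0; j < 4; ++j) {
          if (nr[j] < 0 || nr[j] >= H || nc[j] < 0 || nc[j] >= W) continue;
          if (mask(nr[j], nc[j]) && !lab(nr[j], nc[j])) {
            lab(nr[j], nc[j]) = next;
            stack.push_back(nr[j] + H * nc[j]);
          }
        }
      }
    }
  }
  return lab;
}

// ---------------------------------------------------------------------------
// synthetic forearm scene renderer.  The scene is an analytic function of
// continuous scene coordinates; A (2x3) maps output pixel (r, c, 1) to scene
// coordinates, so the post-series image is rendered by passing the inverse
// of the pre->post pose change.  Rendering the scene analytically (rather
// than warping a raster) keeps ground truth exact.
// ---------------------------------------------------------------------------

static double polyline_dist(const mat& pts, int from, int to, double r, double c) {
  double best = 1e18;
  for (int i = from; i < to - 1; ++i) {
    const double ar = pts(i, 0), ac = pts(i, 1);
    const double br = pts(i + 1, 0), bc = pts(i + 1, 1);
    const double dr = br - ar, dc = bc - ac;
    const double L2 = dr * dr + dc * dc;
    double t = L2 > 0 ? ((r - ar) * dr + (c - ac) * dc) / L2 : 0.0;
    t = std::min(1.0, std::max(0.0, t));
    const double pr = ar + t * dr, pc = ac + t * dc;
    const double d2 = (r - pr) * (r - pr) + (c - pc) * (c - pc);
    if (d2 < best) best = d2;
  }
  return std::sqrt(best);
}

// [[Rcpp::export]]
List cpp_render_scene(int H, int W, NumericMatrix A,
                      NumericVector base_rgb, double base_temp,
                      NumericMatrix tex_vis,   // n x 4: amp, kr, kc, phase (brightness)
                      NumericMatrix tex_th,    // n x 4: amp, kr, kc, phase (degC)
                      NumericMatrix markers,   // n x 5: row, col, radius, square, contrast
                      NumericMatrix marker_rgb,// n x 3
                      double ring_width,
                      NumericMatrix hair_pts, IntegerVector hair_breaks,
                      double hair_dark, double hair_sigma_vis,
                      double hair_cool, double hair_sigma_th,
                      NumericMatrix vessel_pts, IntegerVector vessel_breaks,
                      double vessel_warm, double vessel_sigma,
                      NumericMatrix hotspots   // n x 4: row, col, amp, sigma
                      ) {
  NumericVector vis((size_t)H * W * 3);
  vis.attr("dim") = IntegerVector::create(H, W, 3);
  NumericMatrix th(H, W);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  const int nm = markers.nrow(), nh = hotspots.nrow();
  const int nhair = hair_breaks.size() > 0 ? hair_breaks.size() - 1 : 0;
  const int nves = vessel_breaks.size() > 0 ? vessel_breaks.size() - 1 : 0;
  mat hp(hair_pts.begin(), hair_pts.nrow(), hair_pts.ncol(), true);
  mat vp(vessel_pts.begin(), vessel_pts.nrow(), vessel_pts.ncol(), true);

  // bounding boxes for polylines (with falloff margin)
  const double hmarg = 4.0 * std::max(hair_sigma_vis, hair_sigma_th);
  const double vmarg = 4.0 * vessel_sigma;
  std::vector<double> hb(4 * std::max(nhair, 1)), vb(4 * std::max(nves, 1));
  for (int i = 0; i < nhair; ++i) {
    double r0 = 1e18, r1 = -1e18, c0 = 1e18, c1 = -1e18;
    for (int j = hair_breaks[i]; j < hair_breaks[i + 1]; ++j) {
      r0 = std::min(r0, hp(j, 0)); r1 = std::max(r1, hp(j, 0));
      c0 = std::min(c0, hp(j, 1)); c1 = std::max(c1, hp(j, 1));
    }
    hb[4 * i] = r0 - hmarg; hb[4 * i + 1] = r1 + hmarg;
    hb[4 * i + 2] = c0 - hmarg; hb[4 * i + 3] = c1 + hmarg;
  }
  for (int i = 0; i < nves; ++i) {
    double r0 = 1e18, r1 = -1e18, c0 = 1e18, c1 = -1e18;
    for (int j = vessel_breaks[i]; j < vessel_breaks[i + 1]; ++j) {
      r0 = std::min(r0, vp(j, 0)); r1 = std::max(r1, vp(j, 0));
      c0 = std::min(c0, vp(j, 1)); c1 = std::max(c1, vp(j, 1));
    }
    vb[4 * i] = r0 - vmarg; vb[4 * i + 1] = r1 + vmarg;
    vb[4 * i + 2] = c0 - vmarg; vb[4 * i + 3] = c1 + vmarg;
  }

  const double whalf = ring_width / 2.0;
  double* V = vis.begin();
  const size_t plane = (size_t)H * W;

  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      const double rr = r + 1, cc = c + 1;
      const double sr = a11 * rr + a12 * cc + a13;
      const double sc = a21 * rr + a22 * cc + a23;

      // base skin brightness and thermal baseline
      double bright = 1.0;
      for (int i = 0; i < tex_vis.nrow(); ++i)
        bright += tex_vis(i, 0) * std::sin(tex_vis(i, 1) * sr + tex_vis(i, 2) * sc + tex_vis(i, 3));
      double R = base_rgb[0] * bright, G = base_rgb[1] * bright, B = base_rgb[2] * bright;
      double T = base_temp;
      for (int i = 0; i < tex_th.nrow(); ++i)
        T += tex_th(i, 0) * std::sin(tex_th(i, 1) * sr + tex_th(i, 2) * sc + tex_th(i, 3));

      // highlighter marker rings (visible only; ink has no thermal signature)
      for (int i = 0; i < nm; ++i) {
        const double dr = sr - markers(i, 0), dc = sc - markers(i, 1);
        const double rad = markers(i, 2);
        const double lim = rad + 4 * whalf;
        if (std::fabs(dr) > lim || std::fabs(dc) > lim) continue;
        double dring;
        if (markers(i, 3) > 0.5) {
          dring = std::fabs(std::max(std::fabs(dr), std::fabs(dc)) - rad);
        } else {
          dring = std::fabs(std::sqrt(dr * dr + dc * dc) - rad);
        }
        const double u = dring / whalf;
        if (u > 3) continue;
        const double a = markers(i, 4) * std::exp(-u * u * u * u);
        R = R * (1 - a) + marker_rgb(i, 0) * a;
        G = G * (1 - a) + marker_rgb(i, 1) * a;
        B = B * (1 - a) + marker_rgb(i, 2) * a;
      }

      // hair: darker in visible, cooler in thermal
      for (int i = 0; i < nhair; ++i) {
        if (sr < hb[4 * i] || sr > hb[4 * i + 1] || sc < hb[4 * i + 2] || sc > hb[4 * i + 3]) continue;
        const double d = polyline_dist(hp, hair_breaks[i], hair_breaks[i + 1], sr, sc);
        if (d < 4 * hair_sigma_vis) {
          const double g = std::exp(-d * d / (2 * hair_sigma_vis * hair_sigma_vis));
          const double f = 1.0 - hair_dark * g;
          R *= f; G *= f; B *= f;
        }
        if (d < 4 * hair_sigma_th)
          T -= hair_cool * std::exp(-d * d / (2 * hair_sigma_th * hair_sigma_th));
      }

      // subdermal vessels: warm ridges in thermal only
      for (int i = 0; i < nves; ++i) {
        if (sr < vb[4 * i] || sr > vb[4 * i + 1] || sc < vb[4 * i + 2] || sc > vb[4 * i + 3]) continue;
        const double d = polyline_dist(vp, vessel_breaks[i], vessel_breaks[i + 1], sr, sc);
        if (d < 4 * vessel_sigma)
          T += vessel_warm * std::exp(-d * d / (2 * vessel_sigma * vessel_sigma));
      }

      // reaction hot spots: truncated isotropic Gaussian bumps (post series)
      for (int i = 0; i < nh; ++i) {
        const double dr = sr - hotspots(i, 0), dc = sc - hotspots(i, 1);
        const double sg = hotspots(i, 3);
        const double d2 = dr * dr + dc * dc;
        if (d2 >= 16 * sg * sg) continue;
        const double bump = hotspots(i, 2) * (std::exp(-d2 / (2 * sg * sg)) - std::exp(-8.0));
        if (bump > 0) T += bump;
      }

      const size_t idx = (size_t)H * c + r;
      V[idx] = std::min(1.0, std::max(0.0, R));
      V[plane + idx] = std::min(1.0, std::max(0.0, G));
      V[2 * plane + idx] = std::min(1.0, std::max(0.0, B));
      th(r, c) = T;
    }
  }
  return List::create(_["visible"] = vis, _["thermal"] = th);
}

// visible hives (raised red blisters), rendered separately so they can be
// added to the post series only
// [[Rcpp::export]]
NumericVector cpp_add_hives(NumericVector vis, NumericMatrix A, NumericMatrix hives) {
  IntegerVector d = vis.attr("dim");
  const int H = d[0], W = d[1];
  NumericVector out = clone(vis);
  const double a11 = A(0, 0), a12 = A(0, 1), a13 = A(0, 2);
  const double a21 = A(1, 0), a22 = A(1, 1), a23 = A(1, 2);
  double* V = out.begin();
  const size_t plane = (size_t)H * W;
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r) {
      const double sr = a11 * (r + 1) + a12 * (c + 1) + a13;
      const double sc = a21 * (r + 1) + a22 * (c + 1) + a23;
      double dR = 0, dGB = 0;
      for (int i = 0; i < hives.nrow(); ++i) {
        const double dr = sr - hives(i, 0), dc = sc - hives(i, 1);
        const double sg = hives(i, 3);
        const double d2 = dr * dr + dc * dc;
        if (d2 >= 16 * sg * sg) continue;
        const double g = hives(i, 2) * std::exp(-d2 / (2 * sg * sg));
        dR += g; dGB += 0.4 * g;
      }
      if (dR != 0) {
        const size_t idx = (size_t)H * c + r;
        V[idx] = std::min(1.0, std::max(0.0, V[idx] + dR));
        V[plane + idx] = std::min(1.0, std::max(0.0, V[plane + idx] - dGB));
        V[2 * plane + idx] = std::min(1.0, std::max(0.0, V[2 * plane + idx] - dGB));
      }
    }
  return out;
}

// FNV-1a hash of a raw vector, as a hex string (pipeline manifests)
// [[Rcpp::export]]
std::string cpp_fnv1a(RawVector x) {
  uint64_t h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < x.size(); ++i) {
    h ^= (uint64_t)x[i];
    h *= 1099511628211ULL;
  }
  char buf[17];
  snprintf(buf, sizeof(buf), "%016llx", (unsigned long long)h);
  return std::string(buf);
}
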