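// Fused forward + backward pass of the SSAM network for training.
// Mirrors the R reference implementation in R/model_ops.R exactly:
// column-major frame flattening, channel-major im2col rows with kernel
// offset index k = 3*(dj+1)+(di+1), band-major feature concatenation.
// Gradients are accumulated over the batch; the L2 penalty term is added
// at the R level (the kernel returns pure NLL gradients).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

static const double SELU_L = 1.0507009873554805;
static const double SELU_A = 1.6732632423543772;

static arma::imat make_tab(int g) {
  arma::imat tab(9, g * g);
  tab.fill(-1);
  for (int cell = 0; cell < g * g; ++cell) {
    int i = cell % g, j = cell / g;
    for (int dj = -1; dj <= 1; ++dj) {
      for (int di = -1; di <= 1; ++di) {
        int k = 3 * (dj + 1) + (di + 1);
        int ii = i + di, jj = j + dj;
        if (ii >= 0 && ii < g && jj >= 0 && jj < g) tab(k, cell) = jj * g + ii;
      }
    }
  }
  return tab;
}

static mat im2col(const mat& X, const arma::imat& tab) {
  int C = X.n_rows, n = X.n_cols;
  mat out(9 * C, n, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < 9; ++k)
      for (int cell = 0; cell < n; ++cell) {
        int s = tab(k, cell);
        if (s >= 0) out(c * 9 + k, cell) = X(c, s);
      }
  return out;
}

static mat col2im(const mat& P, const arma::imat& tab, int C) {
  int n = P.n_cols;
  mat out(C, n, fill::zeros);
  for (int c = 0; c < C; ++c)
    for (int k = 0; k < 9; ++k)
      for (int cell = 0; cell < n; ++cell) {
        int s = tab(k, cell);
        if (s >= 0) out(c, s) += P(c * 9 + k, cell);
      }
  return out;
}

static mat selu_m(const mat& U) {
  mat Y = U;
  Y.transform([](double u) {
    return u > 0 ? SELU_L * u : SELU_L * SELU_A * (std::exp(u) - 1.0);
  });
  return Y;
}

static mat selu_prime(const mat& U) {
  mat Y = U;
  Y.transform([](double u) {
    return u > 0 ? SELU_L : SELU_L * SELU_A * std::exp(u);
  });
  return Y;
}

static mat elu_m(const mat& U) {
  mat Y = U;
  Y.transform([](double u) { return u > 0 ? u : std::exp(u) - 1.0; });
  return Y;
}

static mat elu_prime(const mat& U) {
  mat Y = U;
  Y.transform([](double u) { return u > 0 ? 1.0 : std::exp(u); });
  return Y;
}

static vec softmax_v(const vec& x) {
  vec e = exp(x - x.max());
  return e / accu(e);
}

struct Params {
  vec wg, bg, wf, bf;
  mat Wa, W1, W2, W3;
  vec b2, b1;
  std::vector<mat> K1, K2, K3;
  std::vector<vec> c1, c2, c3;
  vec we;
  mat Wd;
  vec bd;
};

static Params parse_params(const List& params) {
  Params P;
  P.wg = as<vec>(params["wg"]); P.bg = as<vec>(params["bg"]);
  P.wf = as<vec>(params["wf"]); P.bf = as<vec>(params["bf"]);
  P.Wa = as<mat>(params["Wa"]);
  P.W1 = as<mat>(params["W1"]); P.W2 = as<mat>(params["W2"]);
  P.b2 = as<vec>(params["b2"]);
  P.W3 = as<mat>(params["W3"]); P.b1 = as<vec>(params["b1"]);
  List conv = params["conv"];
  for (int b = 0; b < 4; ++b) {
    List cb = conv[b];
    P.K1.push_back(as<mat>(cb["K1"])); P.c1.push_back(as<vec>(cb["c1"]));
    P.K2.push_back(as<mat>(cb["K2"])); P.c2.push_back(as<vec>(cb["c2"]));
    P.K3.push_back(as<mat>(cb["K3"])); P.c3.push_back(as<vec>(cb["c3"]));
  }
  P.we = as<vec>(params["we"]);
  P.Wd = as<mat>(params["Wd"]); P.bd = as<vec>(params["bd"]);
  return P;
}

struct Grads {
  vec wg, bg, wf, bf;
  mat Wa, W1, W2, W3;
  vec b2, b1;
  std::vector<mat> K1, K2, K3;
  std::vector<vec> c1, c2, c3;
  vec we;
  mat Wd;
  vec bd;
  explicit Grads(const Params& P) {
    wg = zeros<vec>(P.wg.n_elem); bg = zeros<vec>(P.bg.n_elem);
    wf = zeros<vec>(P.wf.n_elem); bf = zeros<vec>(P.bf.n_elem);
    Wa = zeros<mat>(size(P.Wa));
    W1 = zeros<mat>(size(P.W1)); W2 = zeros<mat>(size(P.W2));
    b2 = zeros<vec>(P.b2.n_elem);
    W3 = zeros<mat>(size(P.W3)); b1 = zeros<vec>(P.b1.n_elem);
    for (int b = 0; b < 4; ++b) {
      K1.push_back(zeros<mat>(size(P.K1[b])));
      c1.push_back(zeros<vec>(P.c1[b].n_elem));
      K2.push_back(zeros<mat>(size(P.K2[b])));
      c2.push_back(zeros<vec>(P.c2[b].n_elem));
      K3.push_back(zeros<mat>(size(P.K3[b])));
      c3.push_back(zeros<vec>(P.c3[b].n_elem));
    }
    we = zeros<vec>(P.we.n_elem);
    Wd = zeros<mat>(size(P.Wd)); bd = zeros<vec>(P.bd.n_elem);
  }
};

// per-band forward cache for one trial
struct BandFwd {
  mat Xb, Zmat, Vmat, U, H, Imat;
  vec alpha, zbar, Cv, smap;
  mat col0, col1, col2, U1, U2, U3, A3;
  vec p, q, gate;
};

// Spatial self-attention over one frame, exploiting the structure of the
// scalar-input 1x1 projections: after removing row-constant terms, row i of
// the score matrix is (a*x_i + c) * x with a = <wg,wf>, c = <bg,wf>, so
// rows sharing a frame value share their softmax row. Only the attended
// mean z_i and the attention-weighted variance v_i per row are needed for
// both the forward pass and the exact parameter gradients:
//   dwg = s_xx * wf,  dbg = s_1x * wf,  dwf = s_xx * wg + s_1x * bg,
//   dbf = 0, with s_xx = sum_i dz_i x_i v_i, s_1x = sum_i dz_i v_i.
// (Row sums of the softmax Jacobian are zero, which kills all terms in the
// row-constant directions.)
static void attend_frame(const vec& x, double a_c, double c_c,
                         vec& z, vec& v) {
  const int n = x.n_elem;
  uvec ord = sort_index(x);
  int i0 = 0;
  while (i0 < n) {
    int i1 = i0;
    const double val = x(ord(i0));
    while (i1 + 1 < n && x(ord(i1 + 1)) == val) ++i1;
    vec s = (a_c * val + c_c) * x;
    vec w = exp(s - s.max());
    const double Zs = accu(w);
    const double zg = dot(w, x) / Zs;
    const double m2 = dot(w, x % x) / Zs;
    for (int ii = i0; ii <= i1; ++ii) {
      z(ord(ii)) = zg;
      v(ord(ii)) = m2 - zg * zg;
    }
    i0 = i1 + 1;
  }
}

// [[Rcpp::export]]
List ssam_batch_cpp(List trials, IntegerVector labels, List params, List cfg,
                    Nullable<NumericMatrix> masks_, bool want_grad) {
  const int g = as<int>(cfg["g"]);
  const int n = g * g;
  const int f1 = as<int>(cfg["f1"]);
  const int f2 = as<int>(cfg["f2"]);
  const int f3 = as<int>(cfg["f3"]);
  const int kE = as<int>(cfg["k"]);
  const int hE = (kE - 1) / 2;
  const Params P = parse_params(params);
  const arma::imat tab = make_tab(g);
  const int B = trials.size();
  const int D = 4 * n * f3;
  const int ncls = P.bd.n_elem;

  mat masks;
  bool use_mask = false;
  if (masks_.isNotNull()) {
    masks = as<mat>(masks_.get());
    use_mask = true;
  }

  Grads G(P);
  vec nll(B, fill::zeros);
  mat probs_out(ncls, B, fill::zeros);

  for (int bi = 0; bi < B; ++bi) {
    List trial = trials[bi];
    std::vector<BandFwd> F(4);
    vec x(D);

    // ---------- forward ----------
    for (int b = 0; b < 4; ++b) {
      BandFwd& C = F[b];
      C.Xb = as<mat>(trial[b]);              // n x T
      const int T = C.Xb.n_cols;
      C.Zmat.set_size(n, T);
      C.Vmat.set_size(n, T);
      const double a_c = dot(P.wg, P.wf);
      const double c_c = dot(P.bg, P.wf);
      for (int t = 0; t < T; ++t) {
        vec xt = C.Xb.col(t);
        vec z(n), v(n);
        attend_frame(xt, a_c, c_c, z, v);
        C.Zmat.col(t) = z;
        C.Vmat.col(t) = v;
      }
      C.zbar = mean(C.Zmat, 1);
      C.Cv = P.Wa * C.zbar;
      C.U = P.W2 * C.Zmat;
      C.U.each_col() += P.W1 * C.Cv + P.b2;
      C.H = elu_m(C.U);
      C.Imat = P.W3 * C.H;
      C.Imat.each_col() += P.b1;
      vec e = sum(C.Imat % C.Zmat, 0).t();
      C.alpha = softmax_v(e);
      C.smap = C.Zmat * C.alpha;

      mat X0 = C.smap.t();                   // 1 x n
      C.col0 = im2col(X0, tab);
      C.U1 = P.K1[b] * C.col0;
      C.U1.each_col() += P.c1[b];
      mat A1 = selu_m(C.U1);
      C.col1 = im2col(A1, tab);
      C.U2 = P.K2[b] * C.col1;
      C.U2.each_col() += P.c2[b];
      mat A2 = selu_m(C.U2);
      C.col2 = im2col(A2, tab);
      C.U3 = P.K3[b] * C.col2;
      C.U3.each_col() += P.c3[b];
      C.A3 = selu_m(C.U3);                   // f3 x n

      C.p = mean(C.A3, 1);
      C.q = zeros<vec>(f3);
      for (int c = 0; c < f3; ++c)
        for (int j = 0; j < kE; ++j) {
          int s = c + j - hE;
          if (s >= 0 && s < f3) C.q(c) += P.we(j) * C.p(s);
        }
      C.gate = 1.0 / (1.0 + exp(-C.q));
      mat Yw = C.A3.each_col() % C.gate;     // f3 x n
      x.subvec(b * n * f3, (b + 1) * n * f3 - 1) = vectorise(Yw.t());
    }

    vec xd = x;
    if (use_mask) xd %= masks.col(bi);
    vec logits = P.Wd * xd + P.bd;
    vec probs = softmax_v(logits);
    probs_out.col(bi) = probs;
    int y = labels[bi];
    if (y >= 0) {
      double p = probs(y);
      if (p < 1e-12) p = 1e-12;
      nll(bi) = -std::log(p);
    } else {
      nll(bi) = NA_REAL;
    }
    if (!want_grad || y < 0) continue;

    // ---------- backward ----------
    vec dlogits = probs;
    dlogits(y) -= 1.0;
    G.Wd += dlogits * xd.t();
    G.bd += dlogits;
    vec dx = P.Wd.t() * dlogits;
    if (use_mask) dx %= masks.col(bi);

    for (int b = 0; b < 4; ++b) {
      BandFwd& C = F[b];
      const int T = C.Xb.n_cols;
      vec seg = dx.subvec(b * n * f3, (b + 1) * n * f3 - 1);
      mat dYw = reshape(seg, n, f3).t();     // f3 x n
      vec dgate = sum(dYw % C.A3, 1);
      mat dA3 = dYw.each_col() % C.gate;
      vec dq = dgate % C.gate % (1.0 - C.gate);
      vec dp = zeros<vec>(f3);
      for (int c = 0; c < f3; ++c)
        for (int j = 0; j < kE; ++j) {
          int s = c + j - hE;
          if (s >= 0 && s < f3) {
            dp(s) += P.we(j) * dq(c);
            G.we(j) += dq(c) * C.p(s);
          }
        }
      dA3.each_col() += dp / (double)n;

      mat dU3 = dA3 % selu_prime(C.U3);
      G.K3[b] += dU3 * C.col2.t();
      G.c3[b] += sum(dU3, 1);
      mat dA2 = col2im(P.K3[b].t() * dU3, tab, f2);
      mat dU2 = dA2 % selu_prime(C.U2);
      G.K2[b] += dU2 * C.col1.t();
      G.c2[b] += sum(dU2, 1);
      mat dA1 = col2im(P.K2[b].t() * dU2, tab, f1);
      mat dU1 = dA1 % selu_prime(C.U1);
      G.K1[b] += dU1 * C.col0.t();
      G.c1[b] += sum(dU1, 1);
      mat dX0 = col2im(P.K1[b].t() * dU1, tab, 1);
      vec dsmap = dX0.row(0).t();            // n

      mat dZ = dsmap * C.alpha.t();          // n x T
      vec dalpha = C.Zmat.t() * dsmap;
      vec de = (dalpha - dot(dalpha, C.alpha)) % C.alpha;
      mat dImat = C.Zmat.each_row() % de.t();
      dZ += C.Imat.each_row() % de.t();
      G.W3 += dImat * C.H.t();
      G.b1 += sum(dImat, 1);
      mat dU = (P.W3.t() * dImat) % elu_prime(C.U);
      G.W2 += dU * C.Zmat.t();
      G.b2 += sum(dU, 1);
      dZ += P.W2.t() * dU;
      vec dUsum = sum(dU, 1);
      G.W1 += dUsum * C.Cv.t();
      vec dCv = P.W1.t() * dUsum;
      G.Wa += dCv * C.zbar.t();
      vec dzbar = P.Wa.t() * dCv;
      dZ.each_col() += dzbar / (double)T;

      for (int t = 0; t < T; ++t) {
        vec xt = C.Xb.col(t);
        vec dz = dZ.col(t);
        const vec v = C.Vmat.col(t);
        const double s_xx = dot(dz % xt, v);
        const double s_1x = dot(dz, v);
        G.wg += s_xx * P.wf;
        G.bg += s_1x * P.wf;
        G.wf += s_xx * P.wg + s_1x * P.bg;
        // bf enters the scores only through row-constant terms; zero grad
      }
    }
  }

  List out = List::create(_["nll"] = nll, _["probs"] = probs_out);
  if (want_grad) {
    List conv(4);
    for (int b = 0; b < 4; ++b) {
      conv[b] = List::create(
        _["K1"] = G.K1[b], _["c1"] = G.c1[b], _["K2"] = G.K2[b],
        _["c2"] = G.c2[b], _["K3"] = G.K3[b], _["c3"] = G.c3[b]);
    }
    CharacterVector bn = CharacterVector::create("theta", "alpha", "beta",
                                                 "gamma");
    conv.attr("names") = bn;
    out["grads"] = List::create(
      _["wg"] = G.wg, _["bg"] = G.bg, _["wf"] = G.wf, _["bf"] = G.bf,
      _["Wa"] = G.Wa, _["W1"] = G.W1, _["W2"] = G.W2, _["b2"] = G.b2,
      _["W3"] = G.W3, _["b1"] = G.b1, _["conv"] = conv, _["we"] = G.we,
      _["Wd"] = G.Wd, _["bd"] = G.bd);
  }
  return out;
}
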