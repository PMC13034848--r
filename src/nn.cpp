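// Neural core for the prior-embedding off-target sub-models.
//
// Architecture (forward): trainable L x 16 embedding holding one scalar
// per (position, pairing-token) cell -> parallel 1-D convolution
// branches with same-length padding plus an identity residual branch
// (Inception block) -> stacked bidirectional LSTM -> flatten -> dense
// head with sigmoid output.  Backpropagation and Adam are implemented
// here so the prior embedding is updated synchronously with the
// downstream weights; all randomness (init, shuffling) lives on the R
// side, keeping this code deterministic.
//
// Layout note: sequence tensors are stored "stacked" as (L*B) x C
// matrices with row index t*B + b, so the per-timestep input
// projections of the convolution and LSTM layers collapse into single
// large GEMMs; only the recurrent term is computed step by step.
// Sigmoid/tanh use a polynomial exp (relative error ~1e-7), which is
// deterministic and much cheaper than libm inside the gate loops.

#include <RcppArmadillo.h>
#include <cstring>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using arma::mat;
using arma::vec;

static inline double fast_exp(double x) {
  if (x > 40.0) x = 40.0;
  if (x < -40.0) x = -40.0;
  const double log2e = 1.4426950408889634;
  const double ln2 = 0.6931471805599453;
  const double t = x * log2e;
  const long long ki = (long long)(t >= 0 ? t + 0.5 : t - 0.5);
  const double r = x - (double)ki * ln2;
  // degree-7 Taylor on |r| <= ln2/2 (relative error ~1e-16 of exp(r))
  double p = 1.0 + r * (1.0 + r * (0.5 + r * (1.0 / 6 + r * (1.0 / 24 +
             r * (1.0 / 120 + r * (1.0 / 720 + r / 5040))))));
  // scale by 2^ki through the IEEE-754 exponent field; p is in
  // [sqrt(1/2), sqrt(2)] and |ki| <= 58, so the result stays normal
  long long bits;
  std::memcpy(&bits, &p, 8);
  bits += ki << 52;
  std::memcpy(&p, &bits, 8);
  return p;
}
static inline double fsig(double x) { return 1.0 / (1.0 + fast_exp(-x)); }
static inline double ftanh(double x) {
  double e = fast_exp(-2.0 * x);
  return (1.0 - e) / (1.0 + e);
}

struct Cfg {
  int L, F, layers, H;
  std::vector<int> ks;
  bool residual, use_conv, use_rnn, emb_train;
  std::vector<int> head;
  double pos_weight;
  int C() const {
    return use_conv ? (int)ks.size() * F + (residual ? 1 : 0) : 1;
  }
  int step_dim() const { return use_rnn ? 2 * H : C(); }
  int flat() const { return L * step_dim(); }
  int rnn_base() const { return 1 + (use_conv ? 2 * (int)ks.size() : 0); }
  int head_base() const {
    return rnn_base() + (use_rnn ? layers * 2 * 3 : 0);
  }
};

static Cfg parse_cfg(const List& c) {
  Cfg cf;
  cf.L = as<int>(c["L"]);
  cf.F = as<int>(c["n_filters"]);
  cf.layers = as<int>(c["rnn_layers"]);
  cf.H = as<int>(c["rnn_hidden"]);
  cf.ks = as<std::vector<int>>(c["kernel_sizes"]);
  cf.residual = as<bool>(c["residual"]);
  cf.use_conv = as<bool>(c["use_conv"]);
  cf.use_rnn = as<bool>(c["use_rnn"]);
  cf.emb_train = as<bool>(c["emb_trainable"]);
  cf.head = as<std::vector<int>>(c["head_sizes"]);
  cf.pos_weight = as<double>(c["pos_weight"]);
  return cf;
}

static std::vector<mat> as_params(const List& p) {
  std::vector<mat> v;
  v.reserve(p.size());
  for (int i = 0; i < p.size(); ++i) v.push_back(as<mat>(p[i]));
  return v;
}

static List to_list(const std::vector<mat>& v) {
  List out(v.size());
  for (size_t i = 0; i < v.size(); ++i) out[i] = wrap(v[i]);
  return out;
}

struct Cache {
  mat xe;                    // B x L embedding lookups
  std::vector<mat> Xc;       // im2col per conv branch, S x k
  mat A;                     // S x C inception output (stacked)
  std::vector<mat> IN;       // LSTM layer inputs, S x Cin
  std::vector<mat> gi, gf, gg, go, cc, tc, hh;  // per layer*2+dir, S x H
  mat OUT;                   // top LSTM output, S x 2H
  mat Xf;                    // B x flat
  std::vector<mat> acts;     // dense layer inputs
  vec p;                     // sigmoid outputs
  mat hbuf, cbuf, hWh;       // recurrence scratch, B x {H,H,4H}
};

static inline mat relu(const mat& z) {
  return arma::clamp(z, 0.0, arma::datum::inf);
}

static void forward(const Cfg& cf, const std::vector<mat>& P,
                    const arma::umat& cols, Cache& ca) {
  const int B = cols.n_rows, L = cf.L, C = cf.C(), S = B * L;
  const mat& E = P[0];
  ca.xe.set_size(B, L);
  for (int i = 0; i < L; ++i)
    for (int b = 0; b < B; ++b)
      ca.xe(b, i) = E(i, cols(b, i));

  // inception block on the stacked layout; vectorise(xe) is exactly the
  // stacked (t*B + b) ordering because xe is B x L column-major
  ca.A.set_size(S, C);
  int pi = 1;
  if (cf.use_conv) {
    ca.Xc.resize(cf.ks.size());
    int ch0 = 0;
    for (size_t kb = 0; kb < cf.ks.size(); ++kb) {
      const int k = cf.ks[kb], pad = (k - 1) / 2;
      mat& Xc = ca.Xc[kb];
      Xc.zeros(S, k);
      for (int j = 0; j < k; ++j)
        for (int t = 0; t < L; ++t) {
          const int src = t + j - pad;
          if (src < 0 || src >= L) continue;
          Xc.submat(t * B, j, t * B + B - 1, j) = ca.xe.col(src);
        }
      mat Z = Xc * P[pi];
      Z.each_row() += P[pi + 1].row(0);
      ca.A.cols(ch0, ch0 + cf.F - 1) = relu(Z);
      pi += 2;
      ch0 += cf.F;
    }
    if (cf.residual) ca.A.col(C - 1) = arma::vectorise(ca.xe);
  } else {
    ca.A.col(0) = arma::vectorise(ca.xe);
  }

  if (cf.use_rnn) {
    const int H = cf.H, nd = cf.layers * 2;
    ca.IN.clear();
    if ((int)ca.gi.size() != nd) {
      ca.gi.assign(nd, mat()); ca.gf.assign(nd, mat());
      ca.gg.assign(nd, mat()); ca.go.assign(nd, mat());
      ca.cc.assign(nd, mat()); ca.tc.assign(nd, mat());
      ca.hh.assign(nd, mat());
    }
    mat cur = ca.A;
    for (int l = 0; l < cf.layers; ++l) {
      ca.IN.push_back(cur);
      mat out(S, 2 * H);
      for (int d = 0; d < 2; ++d) {
        const int idx = l * 2 + d;
        ca.gi[idx].set_size(S, H); ca.gf[idx].set_size(S, H);
        ca.gg[idx].set_size(S, H); ca.go[idx].set_size(S, H);
        ca.cc[idx].set_size(S, H); ca.tc[idx].set_size(S, H);
        ca.hh[idx].set_size(S, H);
        mat Zx = ca.IN[l] * P[pi];
        Zx.each_row() += P[pi + 2].row(0);
        ca.hbuf.zeros(B, H);
        ca.cbuf.zeros(B, H);
        for (int step = 0; step < L; ++step) {
          const int t = (d == 0) ? step : L - 1 - step;
          const int r0 = t * B;
          ca.hWh = ca.hbuf * P[pi + 1];
          for (int hc = 0; hc < H; ++hc) {
            const double* zi = Zx.colptr(hc) + r0;
            const double* zf = Zx.colptr(H + hc) + r0;
            const double* zg = Zx.colptr(2 * H + hc) + r0;
            const double* zo = Zx.colptr(3 * H + hc) + r0;
            const double* wi = ca.hWh.colptr(hc);
            const double* wf = ca.hWh.colptr(H + hc);
            const double* wg = ca.hWh.colptr(2 * H + hc);
            const double* wo = ca.hWh.colptr(3 * H + hc);
            double* cprev = ca.cbuf.colptr(hc);
            double* hout = ca.hbuf.colptr(hc);
            double* pi_ = ca.gi[idx].colptr(hc) + r0;
            double* pf_ = ca.gf[idx].colptr(hc) + r0;
            double* pg_ = ca.gg[idx].colptr(hc) + r0;
            double* po_ = ca.go[idx].colptr(hc) + r0;
            double* pc_ = ca.cc[idx].colptr(hc) + r0;
            double* pt_ = ca.tc[idx].colptr(hc) + r0;
            double* ph_ = ca.hh[idx].colptr(hc) + r0;
            for (int b = 0; b < B; ++b) {
              const double iv = fsig(zi[b] + wi[b]);
              const double fv = fsig(zf[b] + wf[b]);
              const double gv = ftanh(zg[b] + wg[b]);
              const double ov = fsig(zo[b] + wo[b]);
              const double cv = fv * cprev[b] + iv * gv;
              const double tv = ftanh(cv);
              const double hv = ov * tv;
              pi_[b] = iv; pf_[b] = fv; pg_[b] = gv; po_[b] = ov;
              pc_[b] = cv; pt_[b] = tv; ph_[b] = hv;
              cprev[b] = cv; hout[b] = hv;
            }
          }
          out.submat(r0, d * H, r0 + B - 1, (d + 1) * H - 1) = ca.hbuf;
        }
        pi += 3;
      }
      cur = out;
    }
    ca.OUT = cur;
  }

  const int SD = cf.step_dim();
  const mat& top = cf.use_rnn ? ca.OUT : ca.A;
  ca.Xf.set_size(B, cf.flat());
  for (int t = 0; t < L; ++t)
    for (int c = 0; c < SD; ++c)
      ca.Xf.col(t * SD + c) =
        top.col(c).subvec(t * B, t * B + B - 1);

  ca.acts.clear();
  mat a = ca.Xf;
  ca.acts.push_back(a);
  const int nh = (int)cf.head.size();
  for (int i = 0; i < nh; ++i) {
    mat z = a * P[pi];
    z.each_row() += P[pi + 1].row(0);
    pi += 2;
    if (i < nh - 1) {
      a = relu(z);
      ca.acts.push_back(a);
    } else {
      ca.p.set_size(z.n_rows);
      for (arma::uword b = 0; b < z.n_rows; ++b) ca.p(b) = fsig(z(b, 0));
    }
  }
}

static void backward(const Cfg& cf, const std::vector<mat>& P,
                     const arma::umat& cols, const Cache& ca,
                     const vec& dz_out, std::vector<mat>& G) {
  const int B = cols.n_rows, L = cf.L, C = cf.C(), S = B * L;
  const int nh = (int)cf.head.size();
  const int pbase = cf.head_base();

  mat dcur = mat(dz_out);
  mat dXf;
  for (int i = nh - 1; i >= 0; --i) {
    G[pbase + 2 * i] += ca.acts[i].t() * dcur;
    G[pbase + 2 * i + 1] += arma::sum(dcur, 0);
    mat dprev = dcur * P[pbase + 2 * i].t();
    if (i > 0) {
      dprev %= arma::conv_to<mat>::from(ca.acts[i] > 0);
      dcur = dprev;
    } else {
      dXf = dprev;
    }
  }

  const int SD = cf.step_dim();
  mat dtop(S, SD);
  for (int t = 0; t < L; ++t)
    for (int c = 0; c < SD; ++c)
      dtop.col(c).subvec(t * B, t * B + B - 1) = dXf.col(t * SD + c);

  if (cf.use_rnn) {
    const int H = cf.H;
    mat dZ(S, 4 * H), hprev(B, H), dz_t(B, 4 * H);
    for (int l = cf.layers - 1; l >= 0; --l) {
      const int Cin = (l == 0) ? C : 2 * H;
      mat dIN(S, Cin, arma::fill::zeros);
      for (int d = 0; d < 2; ++d) {
        const int idx = l * 2 + d;
        const int pb = cf.rnn_base() + idx * 3;
        mat dhrec(B, H, arma::fill::zeros), dc(B, H, arma::fill::zeros);
        for (int step = L - 1; step >= 0; --step) {
          const int t = (d == 0) ? step : L - 1 - step;
          const int r0 = t * B;
          const int rp = ((d == 0) ? t - 1 : t + 1) * B;
          for (int hc = 0; hc < H; ++hc) {
            const double* dh_in = dtop.colptr(d * H + hc) + r0;
            double* dhr = dhrec.colptr(hc);
            double* dcp = dc.colptr(hc);
            const double* i_ = ca.gi[idx].colptr(hc) + r0;
            const double* f_ = ca.gf[idx].colptr(hc) + r0;
            const double* g_ = ca.gg[idx].colptr(hc) + r0;
            const double* o_ = ca.go[idx].colptr(hc) + r0;
            const double* t_ = ca.tc[idx].colptr(hc) + r0;
            const double* cp =
              (step > 0) ? ca.cc[idx].colptr(hc) + rp : nullptr;
            const double* hp =
              (step > 0) ? ca.hh[idx].colptr(hc) + rp : nullptr;
            double* hpv = hprev.colptr(hc);
            double* dzi = dz_t.colptr(hc);
            double* dzf = dz_t.colptr(H + hc);
            double* dzg = dz_t.colptr(2 * H + hc);
            double* dzo = dz_t.colptr(3 * H + hc);
            for (int b = 0; b < B; ++b) {
              const double dh = dh_in[b] + dhr[b];
              const double dov = dh * t_[b];
              const double dct = dcp[b] + dh * o_[b] * (1.0 - t_[b] * t_[b]);
              const double cprev = (step > 0) ? cp[b] : 0.0;
              dcp[b] = dct * f_[b];
              dzi[b] = dct * g_[b] * i_[b] * (1.0 - i_[b]);
              dzf[b] = dct * cprev * f_[b] * (1.0 - f_[b]);
              dzg[b] = dct * i_[b] * (1.0 - g_[b] * g_[b]);
              dzo[b] = dov * o_[b] * (1.0 - o_[b]);
              hpv[b] = (step > 0) ? hp[b] : 0.0;
            }
          }
          G[pb + 1] += hprev.t() * dz_t;
          dhrec = dz_t * P[pb + 1].t();
          dZ.rows(r0, r0 + B - 1) = dz_t;
        }
        G[pb] += ca.IN[l].t() * dZ;
        G[pb + 2] += arma::sum(dZ, 0);
        dIN += dZ * P[pb].t();
      }
      dtop = dIN;
    }
  }

  // dtop now holds gradients w.r.t. the inception output
  vec dxe_s(S, arma::fill::zeros);  // stacked d/d(embedding lookups)
  int pi = 1;
  if (cf.use_conv) {
    int ch0 = 0;
    for (size_t kb = 0; kb < cf.ks.size(); ++kb) {
      const int k = cf.ks[kb], pad = (k - 1) / 2;
      mat dZc = dtop.cols(ch0, ch0 + cf.F - 1) %
        arma::conv_to<mat>::from(ca.A.cols(ch0, ch0 + cf.F - 1) > 0);
      G[pi] += ca.Xc[kb].t() * dZc;
      G[pi + 1] += arma::sum(dZc, 0);
      mat dXc = dZc * P[pi].t();  // S x k
      for (int j = 0; j < k; ++j)
        for (int t = 0; t < L; ++t) {
          const int src = t + j - pad;
          if (src < 0 || src >= L) continue;
          dxe_s.subvec(src * B, src * B + B - 1) +=
            dXc.col(j).subvec(t * B, t * B + B - 1);
        }
      pi += 2;
      ch0 += cf.F;
    }
    if (cf.residual) dxe_s += dtop.col(C - 1);
  } else {
    dxe_s += dtop.col(0);
  }

  if (cf.emb_train) {
    for (int i = 0; i < L; ++i)
      for (int b = 0; b < B; ++b)
        G[0](i, cols(b, i)) += dxe_s(i * B + b);
  }
}

static arma::umat to_umat0(const IntegerMatrix& cols) {
  arma::umat X(cols.nrow(), cols.ncol());
  for (int j = 0; j < cols.ncol(); ++j)
    for (int i = 0; i < cols.nrow(); ++i)
      X(i, j) = (arma::uword)(cols(i, j) - 1);
  return X;
}

// One full pass over the training data in the given order, with Adam
// updates after every mini-batch.  Returns updated parameters, Adam
// state and the mean batch loss.
// [[Rcpp::export]]
List cpp_train_epoch(List params, List m_in, List v_in, int t0,
                     IntegerMatrix cols, NumericVector y,
                     IntegerVector ord, int batch_size, double lr,
                     List cfg_list) {
  const Cfg cf = parse_cfg(cfg_list);
  std::vector<mat> P = as_params(params);
  std::vector<mat> M = as_params(m_in);
  std::vector<mat> V = as_params(v_in);
  const arma::umat X = to_umat0(cols);
  const vec Y = as<vec>(y);
  const int n = X.n_rows;
  int t = t0;
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8, w = cf.pos_weight;
  double total_loss = 0.0;
  int nb = 0;
  std::vector<mat> G(P.size());
  Cache ca;
  for (int start = 0; start < n; start += batch_size) {
    const int end = std::min(n, start + batch_size);
    const int B = end - start;
    arma::umat xb(B, cf.L);
    vec yb(B);
    for (int b = 0; b < B; ++b) {
      const int r = ord[start + b] - 1;
      xb.row(b) = X.row(r);
      yb(b) = Y(r);
    }
    forward(cf, P, xb, ca);
    vec p = arma::clamp(ca.p, 1e-12, 1.0 - 1e-12);
    total_loss += arma::mean(-(w * yb % arma::log(p) +
                               (1.0 - yb) % arma::log(1.0 - p)));
    ++nb;
    vec dz = (-w * (yb % (1.0 - p)) + (1.0 - yb) % p) / (double)B;
    for (size_t i = 0; i < P.size(); ++i)
      G[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
    backward(cf, P, xb, ca, dz, G);
    ++t;
    const double bc1 = 1.0 - std::pow(b1, t), bc2 = 1.0 - std::pow(b2, t);
    for (size_t i = 0; i < P.size(); ++i) {
      if (i == 0 && !cf.emb_train) continue;
      M[i] = b1 * M[i] + (1.0 - b1) * G[i];
      V[i] = b2 * V[i] + (1.0 - b2) * (G[i] % G[i]);
      P[i] -= lr * (M[i] / bc1) / (arma::sqrt(V[i] / bc2) + eps);
    }
  }
  return List::create(_["params"] = to_list(P), _["m"] = to_list(M),
                      _["v"] = to_list(V), _["t"] = t,
                      _["loss"] = total_loss / std::max(nb, 1));
}

// Deterministic batched inference.
// [[Rcpp::export]]
NumericVector cpp_predict(List params, IntegerMatrix cols, List cfg_list,
                          int batch_size = 1024) {
  const Cfg cf = parse_cfg(cfg_list);
  const std::vector<mat> P = as_params(params);
  const arma::umat X = to_umat0(cols);
  const int n = X.n_rows;
  NumericVector out(n);
  Cache ca;
  for (int start = 0; start < n; start += batch_size) {
    const int end = std::min(n, start + batch_size);
    arma::umat xb = X.rows(start, end - 1);
    forward(cf, P, xb, ca);
    for (int b = 0; b < end - start; ++b) out[start + b] = ca.p(b);
  }
  return out;
}

// Gradients for a single batch without updating parameters (used by
// gradient-flow diagnostics and tests).
// [[Rcpp::export]]
List cpp_gradients(List params, IntegerMatrix cols, NumericVector y,
                   List cfg_list) {
  const Cfg cf = parse_cfg(cfg_list);
  const std::vector<mat> P = as_params(params);
  const arma::umat X = to_umat0(cols);
  const vec Y = as<vec>(y);
  Cache ca;
  forward(cf, P, X, ca);
  vec p = arma::clamp(ca.p, 1e-12, 1.0 - 1e-12);
  const double w = cf.pos_weight;
  vec dz = (-w * (Y % (1.0 - p)) + (1.0 - Y) % p) / (double)X.n_rows;
  std::vector<mat> G(P.size());
  for (size_t i = 0; i < P.size(); ++i)
    G[i] = mat(P[i].n_rows, P[i].n_cols, arma::fill::zeros);
  backward(cf, P, X, ca, dz, G);
  double loss = arma::mean(-(w * Y % arma::log(p) +
                             (1.0 - Y) % arma::log(1.0 - p)));
  return List::create(_["grads"] = to_list(G), _["loss"] = loss);
}
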