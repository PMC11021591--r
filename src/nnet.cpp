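// Forward / backward passes for the 1D CNN -> attention -> GRU seizure
// classifier.  Parameters live in one flat vector so the R-side Adam loop
// stays trivial; layout is defined by layout offsets computed from `dims`.
//
// Conventions (must match the R wrappers):
//   * input batch: cube [channels x samples x batch]
//   * conv blocks: kernel K (odd), zero "same" padding, ReLU, max-pool P/P
//   * attention:   F [T x D] -> softmax(Q K' / sqrt(A)) V, no biases
//   * GRU:         z = sigm(Wz [h; x] + bz), r = sigm(Wr [h; x] + br),
//                  htil = tanh(Wh [r.*h; x] + bh),
//                  h' = (1-z).*h + z.*htil          (rev_gate = 0)
//                  h' = z.*h + (1-z).*htil          (rev_gate = 1)
//   * head:        dropout on final h (inverted, mask supplied by caller),
//                  dense -> scalar logit -> sigmoid
//   * loss:        mean binary cross-entropy, soft labels allowed.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct Dims {
  int C, S, K, P, L, A, H, T, D, G;
  bool use_att, rev_gate;
  std::vector<int> F;       // filters per conv block, F[0] = C
  std::vector<int> Slen;    // sequence length entering each block
};

Dims read_dims(const Rcpp::List& d) {
  Dims x;
  x.C = d["C"]; x.S = d["S"]; x.K = d["K"]; x.P = d["P"];
  x.A = d["A"]; x.H = d["H"];
  x.use_att = Rcpp::as<bool>(d["use_att"]);
  x.rev_gate = Rcpp::as<bool>(d["rev_gate"]);
  Rcpp::IntegerVector f = d["filters"];
  x.L = f.size();
  x.F.resize(x.L + 1);
  x.F[0] = x.C;
  for (int l = 0; l < x.L; ++l) x.F[l + 1] = f[l];
  x.Slen.resize(x.L + 1);
  x.Slen[0] = x.S;
  for (int l = 0; l < x.L; ++l) {
    if (x.Slen[l] % x.P != 0)
      Rcpp::stop("sequence length %d not divisible by pool size %d", x.Slen[l], x.P);
    x.Slen[l + 1] = x.Slen[l] / x.P;
  }
  x.T = x.Slen[x.L];
  x.D = x.F[x.L];
  x.G = x.use_att ? x.A : x.D;       // GRU input width
  if (x.K % 2 != 1) Rcpp::stop("conv kernel must be odd");
  return x;
}

// Offsets of each parameter block inside the flat vector.
struct Layout {
  std::vector<size_t> convW, convb;
  size_t Wq, Wk, Wv, Wz, bz, Wr, br, Wh, bh, wd, bd, total;
};

Layout layout_of(const Dims& d) {
  Layout L;
  size_t o = 0;
  for (int l = 0; l < d.L; ++l) {
    L.convW.push_back(o); o += (size_t)d.F[l + 1] * d.F[l] * d.K;
    L.convb.push_back(o); o += d.F[l + 1];
  }
  if (d.use_att) {
    L.Wq = o; o += (size_t)d.D * d.A;
    L.Wk = o; o += (size_t)d.D * d.A;
    L.Wv = o; o += (size_t)d.D * d.A;
  } else { L.Wq = L.Wk = L.Wv = 0; }
  size_t gin = d.H + d.G;
  L.Wz = o; o += (size_t)d.H * gin; L.bz = o; o += d.H;
  L.Wr = o; o += (size_t)d.H * gin; L.br = o; o += d.H;
  L.Wh = o; o += (size_t)d.H * gin; L.bh = o; o += d.H;
  L.wd = o; o += d.H;
  L.bd = o; o += 1;
  L.total = o;
  return L;
}

// Non-owning matrix view into a flat vector (arma aux-memory constructor).
inline mat view(double* p, size_t off, int r, int c) {
  return mat(p + off, r, c, false, true);
}
inline vec viewv(double* p, size_t off, int n) {
  return vec(p + off, n, false, true);
}

// im2col for "same"-padded 1D conv: input X [Cin x S] -> M [(Cin*K) x S],
// column j holds the K-neighbourhood of sample j across all channels.
mat im2col(const mat& X, int K) {
  int Cin = X.n_rows, S = X.n_cols, pad = (K - 1) / 2;
  mat M(Cin * K, S, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int shift = k - pad;
    int j0 = std::max(0, -shift), j1 = std::min(S, S - shift);
    if (j1 <= j0) continue;
    M.rows(k * Cin, (k + 1) * Cin - 1).cols(j0, j1 - 1) =
        X.cols(j0 + shift, j1 - 1 + shift);
  }
  return M;
}

// scatter dM [(Cin*K) x S] back to dX [Cin x S]
mat col2im(const mat& dM, int Cin, int K) {
  int S = dM.n_cols, pad = (K - 1) / 2;
  mat dX(Cin, S, fill::zeros);
  for (int k = 0; k < K; ++k) {
    int shift = k - pad;
    int j0 = std::max(0, -shift), j1 = std::min(S, S - shift);
    if (j1 <= j0) continue;
    dX.cols(j0 + shift, j1 - 1 + shift) +=
        dM.rows(k * Cin, (k + 1) * Cin - 1).cols(j0, j1 - 1);
  }
  return dX;
}

// max-pool width/stride P; records argmax column for backward
mat maxpool(const mat& X, int P, umat& arg) {
  int R = X.n_rows, S = X.n_cols, So = S / P;
  mat Y(R, So);
  arg.set_size(R, So);
  for (int j = 0; j < So; ++j) {
    for (int r = 0; r < R; ++r) {
      int best = j * P;
      double bv = X(r, best);
      for (int k = 1; k < P; ++k)
        if (X(r, j * P + k) > bv) { bv = X(r, j * P + k); best = j * P + k; }
      Y(r, j) = bv; arg(r, j) = best;
    }
  }
  return Y;
}

inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

// per-sample caches kept between forward and backward
struct SampleCache {
  std::vector<mat> act;    // post-ReLU pre-pool activation per block
  std::vector<mat> pooled; // post-pool per block (pooled[L-1] feeds attention)
  std::vector<umat> parg;  // pool argmax per block
  mat Fseq;                // [T x D] sequence entering attention / GRU
  mat Q, Km, V, Aw;        // attention caches (Aw = softmax weights [T x T])
  mat G;                   // [T x G] GRU input sequence
};

void conv_forward(const Dims& d, double* pp, const Layout& ly,
                  const mat& X, SampleCache& sc) {
  sc.act.resize(d.L); sc.pooled.resize(d.L); sc.parg.resize(d.L);
  mat cur = X;
  for (int l = 0; l < d.L; ++l) {
    mat W = view(pp, ly.convW[l], d.F[l + 1], d.F[l] * d.K);
    vec b = viewv(pp, ly.convb[l], d.F[l + 1]);
    mat M = im2col(cur, d.K);
    mat Apre = W * M;
    Apre.each_col() += b;
    sc.act[l] = clamp(Apre, 0.0, datum::inf);            // ReLU
    sc.pooled[l] = maxpool(sc.act[l], d.P, sc.parg[l]);
    cur = sc.pooled[l];
  }
  sc.Fseq = cur.t();                                     // [T x D]
}

void attention_forward(const Dims& d, double* pp, const Layout& ly,
                       SampleCache& sc) {
  if (!d.use_att) { sc.G = sc.Fseq; return; }
  mat Wq = view(pp, ly.Wq, d.D, d.A);
  mat Wk = view(pp, ly.Wk, d.D, d.A);
  mat Wv = view(pp, ly.Wv, d.D, d.A);
  sc.Q = sc.Fseq * Wq; sc.Km = sc.Fseq * Wk; sc.V = sc.Fseq * Wv;
  mat Sc = sc.Q * sc.Km.t() / std::sqrt((double)d.A);
  Sc.each_col() -= max(Sc, 1);                           // row-wise stabilise
  mat E = exp(Sc);
  vec rs = sum(E, 1);
  E.each_col() /= rs;
  sc.Aw = E;
  sc.G = sc.Aw * sc.V;                                   // [T x A]
}

// attention backward: dG -> dF, accumulate projection grads
mat attention_backward(const Dims& d, double* pp, const Layout& ly,
                       double* gp, const SampleCache& sc, const mat& dG) {
  if (!d.use_att) return dG;
  mat Wq = view(pp, ly.Wq, d.D, d.A);
  mat Wk = view(pp, ly.Wk, d.D, d.A);
  mat Wv = view(pp, ly.Wv, d.D, d.A);
  mat gWq = view(gp, ly.Wq, d.D, d.A);
  mat gWk = view(gp, ly.Wk, d.D, d.A);
  mat gWv = view(gp, ly.Wv, d.D, d.A);
  mat dA = dG * sc.V.t();                                // [T x T]
  mat dV = sc.Aw.t() * dG;                               // [T x A]
  // softmax rows: ds = a .* (da - sum(da .* a))
  vec rowdot = sum(dA % sc.Aw, 1);
  mat dS = sc.Aw % (dA.each_col() - rowdot);
  dS /= std::sqrt((double)d.A);
  mat dQ = dS * sc.Km;
  mat dK = dS.t() * sc.Q;
  gWq += sc.Fseq.t() * dQ;
  gWk += sc.Fseq.t() * dK;
  gWv += sc.Fseq.t() * dV;
  return dQ * Wq.t() + dK * Wk.t() + dV * Wv.t();        // dF [T x D]
}

// conv backward per sample: dF (w.r.t. pooled[L-1]) -> grads (+ dX if asked)
mat conv_backward(const Dims& d, double* pp, const Layout& ly, double* gp,
                  const mat& X, const SampleCache& sc, mat dPooled,
                  bool want_dx) {
  mat dcur = dPooled;                                    // [F_L x T]
  for (int l = d.L - 1; l >= 0; --l) {
    // pool backward
    mat dAct(size(sc.act[l]), fill::zeros);
    for (uword j = 0; j < dcur.n_cols; ++j)
      for (uword r = 0; r < dcur.n_rows; ++r)
        dAct(r, sc.parg[l](r, j)) += dcur(r, j);
    // ReLU backward
    dAct.elem(find(sc.act[l] == 0)).zeros();
    // conv backward
    const mat& below = (l == 0) ? X : sc.pooled[l - 1];
    mat M = im2col(below, d.K);
    mat gW = view(gp, ly.convW[l], d.F[l + 1], d.F[l] * d.K);
    vec gb = viewv(gp, ly.convb[l], d.F[l + 1]);
    gW += dAct * M.t();
    gb += sum(dAct, 1);
    if (l == 0 && !want_dx) return mat();
    mat W = view(pp, ly.convW[l], d.F[l + 1], d.F[l] * d.K);
    mat dM = W.t() * dAct;
    dcur = col2im(dM, d.F[l], d.K);
  }
  return dcur;                                           // dX [C x S]
}

} // namespace

// [[Rcpp::export]]
int nn_n_params(Rcpp::List dims) {
  Dims d = read_dims(dims);
  return (int)layout_of(d).total;
}

// Forward pass.  dropout_mask: H x B 0/1 matrix (training) or 0 x 0 (off).
// [[Rcpp::export]]
Rcpp::NumericVector nn_forward(Rcpp::NumericVector params, Rcpp::List dims,
                               arma::cube X, arma::mat dropout_mask,
                               double dropout_rate) {
  Dims d = read_dims(dims);
  Layout ly = layout_of(d);
  if (params.size() != (R_xlen_t)ly.total) Rcpp::stop("bad parameter length");
  if ((int)X.n_rows != d.C || (int)X.n_cols != d.S)
    Rcpp::stop("input shape [%d x %d] does not match model [%d x %d]",
               (int)X.n_rows, (int)X.n_cols, d.C, d.S);
  double* pp = params.begin();
  int B = X.n_slices;
  bool drop = dropout_mask.n_elem > 0;

  mat Wz = view(pp, ly.Wz, d.H, d.H + d.G); vec bz = viewv(pp, ly.bz, d.H);
  mat Wr = view(pp, ly.Wr, d.H, d.H + d.G); vec br = viewv(pp, ly.br, d.H);
  mat Wh = view(pp, ly.Wh, d.H, d.H + d.G); vec bh = viewv(pp, ly.bh, d.H);
  vec wd = viewv(pp, ly.wd, d.H);
  double bd = params[ly.bd];

  // conv + attention per sample, GRU batched over T
  cube Gseq(d.G, B, d.T);
  for (int i = 0; i < B; ++i) {
    SampleCache sc;
    conv_forward(d, pp, ly, X.slice(i), sc);
    attention_forward(d, pp, ly, sc);
    for (int t = 0; t < d.T; ++t) Gseq.slice(t).col(i) = sc.G.row(t).t();
  }
  mat Hst(d.H, B, fill::zeros);
  for (int t = 0; t < d.T; ++t) {
    mat U = join_cols(Hst, Gseq.slice(t));
    mat Z = sigm(Wz * U + repmat(bz, 1, B));
    mat R = sigm(Wr * U + repmat(br, 1, B));
    mat U2 = join_cols(R % Hst, Gseq.slice(t));
    mat Ht = tanh(Wh * U2 + repmat(bh, 1, B));
    Hst = d.rev_gate ? mat(Z % Hst + (1.0 - Z) % Ht)
                     : mat((1.0 - Z) % Hst + Z % Ht);
  }
  if (drop) Hst = (Hst % dropout_mask) / (1.0 - dropout_rate);
  rowvec logit = wd.t() * Hst + bd;
  Rcpp::NumericVector out(B);
  for (int i = 0; i < B; ++i) out[i] = 1.0 / (1.0 + std::exp(-logit(i)));
  return out;
}

// Loss + gradients.  Returns list(loss, probs, grad, xgrad?).
// [[Rcpp::export]]
Rcpp::List nn_grad(Rcpp::NumericVector params, Rcpp::List dims,
                   arma::cube X, arma::vec y, arma::mat dropout_mask,
                   double dropout_rate, bool want_x_grad) {
  Dims d = read_dims(dims);
  Layout ly = layout_of(d);
  if (params.size() != (R_xlen_t)ly.total) Rcpp::stop("bad parameter length");
  double* pp = params.begin();
  int B = X.n_slices;
  if ((int)y.n_elem != B) Rcpp::stop("labels do not match batch");
  bool drop = dropout_mask.n_elem > 0;

  Rcpp::NumericVector grad(ly.total);
  double* gp = grad.begin();

  mat Wz = view(pp, ly.Wz, d.H, d.H + d.G); vec bz = viewv(pp, ly.bz, d.H);
  mat Wr = view(pp, ly.Wr, d.H, d.H + d.G); vec br = viewv(pp, ly.br, d.H);
  mat Wh = view(pp, ly.Wh, d.H, d.H + d.G); vec bh = viewv(pp, ly.bh, d.H);
  vec wd = viewv(pp, ly.wd, d.H);
  double bd = params[ly.bd];
  mat gWz = view(gp, ly.Wz, d.H, d.H + d.G); vec gbz = viewv(gp, ly.bz, d.H);
  mat gWr = view(gp, ly.Wr, d.H, d.H + d.G); vec gbr = viewv(gp, ly.br, d.H);
  mat gWh = view(gp, ly.Wh, d.H, d.H + d.G); vec gbh = viewv(gp, ly.bh, d.H);
  vec gwd = viewv(gp, ly.wd, d.H);

  // ---- forward, caching ----
  std::vector<SampleCache> caches(B);
  cube Gseq(d.G, B, d.T);
  for (int i = 0; i < B; ++i) {
    conv_forward(d, pp, ly, X.slice(i), caches[i]);
    attention_forward(d, pp, ly, caches[i]);
    for (int t = 0; t < d.T; ++t)
      Gseq.slice(t).col(i) = caches[i].G.row(t).t();
  }
  cube Zs(d.H, B, d.T), Rs(d.H, B, d.T), Htils(d.H, B, d.T), Hs(d.H, B, d.T);
  mat Hprev(d.H, B, fill::zeros);
  for (int t = 0; t < d.T; ++t) {
    mat U = join_cols(Hprev, Gseq.slice(t));
    mat Z = sigm(Wz * U + repmat(bz, 1, B));
    mat R = sigm(Wr * U + repmat(br, 1, B));
    mat U2 = join_cols(R % Hprev, Gseq.slice(t));
    mat Ht = tanh(Wh * U2 + repmat(bh, 1, B));
    Zs.slice(t) = Z; Rs.slice(t) = R; Htils.slice(t) = Ht;
    Hprev = d.rev_gate ? mat(Z % Hprev + (1.0 - Z) % Ht)
                       : mat((1.0 - Z) % Hprev + Z % Ht);
    Hs.slice(t) = Hprev;
  }
  mat Hfin = Hs.slice(d.T - 1);
  mat Hdrop = drop ? mat((Hfin % dropout_mask) / (1.0 - dropout_rate)) : Hfin;
  rowvec logit = wd.t() * Hdrop + bd;
  vec p(B), loss_i(B);
  for (int i = 0; i < B; ++i) {
    double s = logit(i);
    p(i) = 1.0 / (1.0 + std::exp(-s));
    // softplus(s) - y*s, stable for both signs
    double sp = s > 0 ? s + std::log1p(std::exp(-s)) : std::log1p(std::exp(s));
    loss_i(i) = sp - y(i) * s;
  }
  double loss = mean(loss_i);
  if (!std::isfinite(loss)) {
    return Rcpp::List::create(Rcpp::Named("loss") = loss,
                              Rcpp::Named("probs") = Rcpp::wrap(p),
                              Rcpp::Named("grad") = R_NilValue);
  }

  // ---- backward ----
  rowvec dlogit = (p - y).t() / (double)B;
  gwd += Hdrop * dlogit.t();
  gp[ly.bd] += accu(dlogit);
  mat dH = wd * dlogit;                       // [H x B] grad w.r.t. Hdrop
  if (drop) dH = (dH % dropout_mask) / (1.0 - dropout_rate);

  cube dGseq(d.G, B, d.T, fill::zeros);
  for (int t = d.T - 1; t >= 0; --t) {
    mat Hm1 = (t == 0) ? mat(d.H, B, fill::zeros) : Hs.slice(t - 1);
    const mat& Z = Zs.slice(t);
    const mat& R = Rs.slice(t);
    const mat& Ht = Htils.slice(t);
    mat dZ, dHt, dHm1;
    if (d.rev_gate) {
      dZ = dH % (Hm1 - Ht);
      dHt = dH % (1.0 - Z);
      dHm1 = dH % Z;
    } else {
      dZ = dH % (Ht - Hm1);
      dHt = dH % Z;
      dHm1 = dH % (1.0 - Z);
    }
    mat dpre_h = dHt % (1.0 - Ht % Ht);
    mat dpre_z = dZ % Z % (1.0 - Z);
    mat U = join_cols(Hm1, Gseq.slice(t));
    mat U2 = join_cols(R % Hm1, Gseq.slice(t));
    gWh += dpre_h * U2.t(); gbh += sum(dpre_h, 1);
    gWz += dpre_z * U.t();  gbz += sum(dpre_z, 1);
    mat dU2 = Wh.t() * dpre_h;                 // [(H+G) x B]
    mat dRH = dU2.rows(0, d.H - 1);
    dGseq.slice(t) += dU2.rows(d.H, d.H + d.G - 1);
    mat dR = dRH % Hm1;
    dHm1 += dRH % R;
    mat dpre_r = dR % R % (1.0 - R);
    gWr += dpre_r * U.t();  gbr += sum(dpre_r, 1);
    mat dU = Wz.t() * dpre_z + Wr.t() * dpre_r;
    dHm1 += dU.rows(0, d.H - 1);
    dGseq.slice(t) += dU.rows(d.H, d.H + d.G - 1);
    dH = dHm1;
  }

  cube xgrad;
  if (want_x_grad) xgrad.set_size(d.C, d.S, B);
  for (int i = 0; i < B; ++i) {
    mat dG(d.T, d.G);
    for (int t = 0; t < d.T; ++t) dG.row(t) = dGseq.slice(t).col(i).t();
    mat dF = attention_backward(d, pp, ly, gp, caches[i], dG);
    mat dX = conv_backward(d, pp, ly, gp, X.slice(i), caches[i],
                           dF.t(), want_x_grad);
    if (want_x_grad) xgrad.slice(i) = dX;
  }

  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loss") = loss,
      Rcpp::Named("probs") = Rcpp::wrap(p),
      Rcpp::Named("grad") = grad);
  if (want_x_grad) out["xgrad"] = xgrad;
  return out;
}
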