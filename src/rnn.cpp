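// Batched forward/backward passes for the two-branch recurrent splicing model.
//
// Layout conventions (shared with the R side):
//   * minibatch input cubes are B x C x T (events x channels x positions)
//   * concatenated gate weights: Wx is C x (G*H), Wh is H x (G*H), b is (G*H)
//   * gate order: LSTM f,i,o,g ; GRU z,r,n ; simple RNN a single block
//   * cell codes: 0 = lstm, 1 = gru, 2 = simple
//
// The merge layer consumes the two branch hidden-state sequences concatenated
// along the position axis (acceptor first, donor second); its final hidden
// state goes through (inverted) dropout and a two-unit softmax head.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static inline mat sigm(const mat& x) { return 1.0 / (1.0 + exp(-x)); }

struct SeqCache {
  cube H;              // B x H x T hidden states
  cube f, i, o, g, c;  // lstm gates and cell state
  cube z, r, n, rH;    // gru gates, candidate, and r (*) h_prev
};

static void seq_forward(int cell, const cube& X, const mat& Wx, const mat& Wh,
                        const rowvec& b, SeqCache& K) {
  const uword B = X.n_rows, T = X.n_slices, H = Wh.n_rows;
  K.H.set_size(B, H, T);
  mat h_prev(B, H, fill::zeros);
  if (cell == 0) {
    K.f.set_size(B, H, T); K.i.set_size(B, H, T); K.o.set_size(B, H, T);
    K.g.set_size(B, H, T); K.c.set_size(B, H, T);
    mat c_prev(B, H, fill::zeros);
    for (uword t = 0; t < T; ++t) {
      mat A = X.slice(t) * Wx + h_prev * Wh;
      A.each_row() += b;
      mat f = sigm(A.cols(0, H - 1));
      mat i = sigm(A.cols(H, 2 * H - 1));
      mat o = sigm(A.cols(2 * H, 3 * H - 1));
      mat g = tanh(A.cols(3 * H, 4 * H - 1));
      mat c = f % c_prev + i % g;
      mat h = o % tanh(c);
      K.f.slice(t) = f; K.i.slice(t) = i; K.o.slice(t) = o;
      K.g.slice(t) = g; K.c.slice(t) = c; K.H.slice(t) = h;
      h_prev = h; c_prev = c;
    }
  } else if (cell == 1) {
    K.z.set_size(B, H, T); K.r.set_size(B, H, T);
    K.n.set_size(B, H, T); K.rH.set_size(B, H, T);
    for (uword t = 0; t < T; ++t) {
      mat Azr = X.slice(t) * Wx.cols(0, 2 * H - 1) + h_prev * Wh.cols(0, 2 * H - 1);
      Azr.each_row() += b.cols(0, 2 * H - 1);
      mat z = sigm(Azr.cols(0, H - 1));
      mat r = sigm(Azr.cols(H, 2 * H - 1));
      mat rH = r % h_prev;
      mat An = X.slice(t) * Wx.cols(2 * H, 3 * H - 1) + rH * Wh.cols(2 * H, 3 * H - 1);
      An.each_row() += b.cols(2 * H, 3 * H - 1);
      mat n = tanh(An);
      mat h = (1.0 - z) % h_prev + z % n;
      K.z.slice(t) = z; K.r.slice(t) = r; K.n.slice(t) = n;
      K.rH.slice(t) = rH; K.H.slice(t) = h;
      h_prev = h;
    }
  } else {
    for (uword t = 0; t < T; ++t) {
      mat A = X.slice(t) * Wx + h_prev * Wh;
      A.each_row() += b;
      mat h = tanh(A);
      K.H.slice(t) = h;
      h_prev = h;
    }
  }
}

// dHext carries the external (downstream) gradient for every time step's
// hidden state; recurrent gradients are accumulated internally.
static void seq_backward(int cell, const cube& X, const mat& Wx, const mat& Wh,
                         const SeqCache& K, const cube& dHext,
                         mat& gWx, mat& gWh, rowvec& gb, cube* dX) {
  const uword B = X.n_rows, T = X.n_slices, H = Wh.n_rows;
  gWx.zeros(Wx.n_rows, Wx.n_cols);
  gWh.zeros(Wh.n_rows, Wh.n_cols);
  gb.zeros(Wx.n_cols);
  mat dh_rec(B, H, fill::zeros), dc_rec(B, H, fill::zeros);
  for (uword t = T; t-- > 0;) {
    mat h_prev = (t > 0) ? K.H.slice(t - 1) : mat(B, H, fill::zeros);
    mat dh = dHext.slice(t) + dh_rec;
    if (cell == 0) {
      const mat& f = K.f.slice(t); const mat& i = K.i.slice(t);
      const mat& o = K.o.slice(t); const mat& g = K.g.slice(t);
      const mat& c = K.c.slice(t);
      mat c_prev = (t > 0) ? K.c.slice(t - 1) : mat(B, H, fill::zeros);
      mat tc = tanh(c);
      mat do_ = dh % tc;
      mat dc = dc_rec + dh % o % (1.0 - tc % tc);
      mat df = dc % c_prev;
      mat di = dc % g;
      mat dg = dc % i;
      dc_rec = dc % f;
      mat dA = join_rows(df % f % (1.0 - f), di % i % (1.0 - i),
                         do_ % o % (1.0 - o), dg % (1.0 - g % g));
      gWx += X.slice(t).t() * dA;
      gWh += h_prev.t() * dA;
      gb += sum(dA, 0);
      dh_rec = dA * Wh.t();
      if (dX) dX->slice(t) = dA * Wx.t();
    } else if (cell == 1) {
      const mat& z = K.z.slice(t); const mat& r = K.r.slice(t);
      const mat& n = K.n.slice(t); const mat& rH = K.rH.slice(t);
      mat dz = dh % (n - h_prev);
      mat dn = dh % z;
      mat dh_prev = dh % (1.0 - z);
      mat dan = dn % (1.0 - n % n);
      mat d_rH = dan * Wh.cols(2 * H, 3 * H - 1).t();
      mat dr = d_rH % h_prev;
      dh_prev += d_rH % r;
      mat dAzr = join_rows(dz % z % (1.0 - z), dr % r % (1.0 - r));
      dh_prev += dAzr * Wh.cols(0, 2 * H - 1).t();
      mat dAll = join_rows(dAzr, dan);
      gWx += X.slice(t).t() * dAll;
      gWh.cols(0, 2 * H - 1) += h_prev.t() * dAzr;
      gWh.cols(2 * H, 3 * H - 1) += rH.t() * dan;
      gb += sum(dAll, 0);
      dh_rec = dh_prev;
      if (dX) dX->slice(t) = dAll * Wx.t();
    } else {
      const mat& h = K.H.slice(t);
      mat dA = dh % (1.0 - h % h);
      gWx += X.slice(t).t() * dA;
      gWh += h_prev.t() * dA;
      gb += sum(dA, 0);
      dh_rec = dA * Wh.t();
      if (dX) dX->slice(t) = dA * Wx.t();
    }
  }
}

// Full two-branch pass over one minibatch. `mask` is the inverted-dropout
// mask for the final merge hidden state (0 x 0 matrix = identity, i.e.
// inference). `y` holds class indices in {0,1} (1 = included); length 0
// skips the loss. Gradients require `y`.
// [[Rcpp::export]]
Rcpp::List rnn_pass_cpp(const arma::cube& Xa, const arma::cube& Xd,
                        const arma::mat& WxA, const arma::mat& WhA, const arma::rowvec& bA,
                        const arma::mat& WxD, const arma::mat& WhD, const arma::rowvec& bD,
                        const arma::mat& WxM, const arma::mat& WhM, const arma::rowvec& bM,
                        const arma::mat& Wy, const arma::rowvec& by,
                        int cell, const arma::mat& mask, const arma::ivec& y,
                        bool want_grads) {
  const uword B = Xa.n_rows, Ta = Xa.n_slices, Td = Xd.n_slices;
  const uword Hb = WhA.n_rows, Hm = WhM.n_rows;
  if (Xd.n_rows != B) Rcpp::stop("acceptor/donor batch sizes differ");
  SeqCache Ka, Kd, Km;
  seq_forward(cell, Xa, WxA, WhA, bA, Ka);
  seq_forward(cell, Xd, WxD, WhD, bD, Kd);
  cube M(B, Hb, Ta + Td);
  for (uword t = 0; t < Ta; ++t) M.slice(t) = Ka.H.slice(t);
  for (uword t = 0; t < Td; ++t) M.slice(Ta + t) = Kd.H.slice(t);
  seq_forward(cell, M, WxM, WhM, bM, Km);
  mat hT = Km.H.slice(Ta + Td - 1);
  const bool use_mask = mask.n_elem > 0;
  if (use_mask) hT %= mask;
  mat logits = hT * Wy;
  logits.each_row() += by;
  mat E = exp(logits - repmat(max(logits, 1), 1, 2));
  mat P = E / repmat(sum(E, 1), 1, 2);
  vec p = P.col(1);
  double loss = NA_REAL;
  if (y.n_elem == B) {
    vec py(B);
    for (uword b = 0; b < B; ++b) py(b) = P(b, (uword)y(b));
    loss = -mean(log(clamp(py, 1e-12, 1.0)));
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("p") = p,
                                      Rcpp::Named("loss") = loss);
  if (!want_grads) return out;
  if (y.n_elem != B) Rcpp::stop("labels required for gradient computation");
  mat dlog = P;
  for (uword b = 0; b < B; ++b) dlog(b, (uword)y(b)) -= 1.0;
  dlog /= (double)B;
  mat gWy = hT.t() * dlog;
  rowvec gby = sum(dlog, 0);
  mat dhT = dlog * Wy.t();
  if (use_mask) dhT %= mask;
  cube dHm(B, Hm, Ta + Td, fill::zeros);
  dHm.slice(Ta + Td - 1) = dhT;
  mat gWxM, gWhM; rowvec gbM;
  cube dM(B, Hb, Ta + Td);
  seq_backward(cell, M, WxM, WhM, Km, dHm, gWxM, gWhM, gbM, &dM);
  cube dHa(B, Hb, Ta), dHd(B, Hb, Td);
  for (uword t = 0; t < Ta; ++t) dHa.slice(t) = dM.slice(t);
  for (uword t = 0; t < Td; ++t) dHd.slice(t) = dM.slice(Ta + t);
  mat gWxA, gWhA; rowvec gbA;
  mat gWxD, gWhD; rowvec gbD;
  seq_backward(cell, Xa, WxA, WhA, Ka, dHa, gWxA, gWhA, gbA, nullptr);
  seq_backward(cell, Xd, WxD, WhD, Kd, dHd, gWxD, gWhD, gbD, nullptr);
  out["grads"] = Rcpp::List::create(
      Rcpp::Named("acceptor") = Rcpp::List::create(
          Rcpp::Named("Wx") = gWxA, Rcpp::Named("Wh") = gWhA,
          Rcpp::Named("b") = Rcpp::NumericVector(gbA.begin(), gbA.end())),
      Rcpp::Named("donor") = Rcpp::List::create(
          Rcpp::Named("Wx") = gWxD, Rcpp::Named("Wh") = gWhD,
          Rcpp::Named("b") = Rcpp::NumericVector(gbD.begin(), gbD.end())),
      Rcpp::Named("merge") = Rcpp::List::create(
          Rcpp::Named("Wx") = gWxM, Rcpp::Named("Wh") = gWhM,
          Rcpp::Named("b") = Rcpp::NumericVector(gbM.begin(), gbM.end())),
      Rcpp::Named("head") = Rcpp::List::create(
          Rcpp::Named("Wy") = gWy,
          Rcpp::Named("by") = Rcpp::NumericVector(gby.begin(), gby.end())));
  return out;
}
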