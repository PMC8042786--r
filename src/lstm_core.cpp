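// Fused inner loops of the masked, batched LSTM used by the trainer.
// One direction per call; the four gates share a single matrix product.
// The R level owns parameter layout, pooling, attention and the optimiser.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline mat sigm(const mat& z) { return 1.0 / (1.0 + exp(-z)); }

// [[Rcpp::export]]
Rcpp::List lstm_dir_forward_cpp(const arma::cube& X, const arma::mat& mask,
                                const arma::mat& Wall, const arma::mat& Uall,
                                const bool reverse) {
  const uword T = X.n_slices, B = X.n_rows, H = Uall.n_rows;
  cube I(B, H, T), F(B, H, T), O(B, H, T), G(B, H, T), TC(B, H, T);
  cube HP(B, H, T), CP(B, H, T), HA(B, H, T);
  mat h(B, H, fill::zeros), c(B, H, fill::zeros);

  for (uword s = 0; s < T; ++s) {
    const uword pos = reverse ? (T - 1 - s) : s;
    const mat x = X.slice(pos);
    const mat M = repmat(mask.col(pos), 1, H);
    const mat pre = x * Wall + h * Uall;
    const mat i = sigm(pre.cols(0, H - 1));
    const mat f = sigm(pre.cols(H, 2 * H - 1));
    const mat o = sigm(pre.cols(2 * H, 3 * H - 1));
    const mat g = tanh(pre.cols(3 * H, 4 * H - 1));
    const mat c_new = f % c + i % g;
    const mat tc = tanh(c_new);
    HP.slice(s) = h;
    CP.slice(s) = c;
    I.slice(s) = i;
    F.slice(s) = f;
    O.slice(s) = o;
    G.slice(s) = g;
    TC.slice(s) = tc;
    c = M % c_new + (1.0 - M) % c;
    h = M % (o % tc) + (1.0 - M) % h;
    HA.slice(pos) = h;
  }
  return Rcpp::List::create(
    Rcpp::Named("states") = HA, Rcpp::Named("i") = I, Rcpp::Named("f") = F,
    Rcpp::Named("o") = O, Rcpp::Named("g") = G, Rcpp::Named("tc") = TC,
    Rcpp::Named("h_prev") = HP, Rcpp::Named("c_prev") = CP);
}

// [[Rcpp::export]]
Rcpp::List lstm_dir_backward_cpp(const arma::cube& X, const arma::mat& mask,
                                 const arma::mat& Uall, const Rcpp::List& fw,
                                 const arma::cube& d_states,
                                 const bool reverse) {
  const cube I = fw["i"], F = fw["f"], O = fw["o"], G = fw["g"];
  const cube TC = fw["tc"], HP = fw["h_prev"], CP = fw["c_prev"];
  const uword T = X.n_slices, B = X.n_rows, H = Uall.n_rows, d = X.n_cols;

  mat gW(d, 4 * H, fill::zeros), gU(H, 4 * H, fill::zeros);
  mat dh_next(B, H, fill::zeros), dc_next(B, H, fill::zeros);
  mat pre(B, 4 * H);

  for (sword s = T - 1; s >= 0; --s) {
    const uword pos = reverse ? (T - 1 - s) : s;
    const mat x = X.slice(pos);
    const mat M = repmat(mask.col(pos), 1, H);
    const mat dh_total = dh_next + d_states.slice(pos);
    const mat dh_new = M % dh_total;
    const mat& i = I.slice(s);
    const mat& f = F.slice(s);
    const mat& o = O.slice(s);
    const mat& g = G.slice(s);
    const mat& tc = TC.slice(s);
    const mat dc_new = M % dc_next + dh_new % o % (1.0 - tc % tc);
    pre.cols(0, H - 1) = (dc_new % g) % i % (1.0 - i);
    pre.cols(H, 2 * H - 1) = (dc_new % CP.slice(s)) % f % (1.0 - f);
    pre.cols(2 * H, 3 * H - 1) = (dh_new % tc) % o % (1.0 - o);
    pre.cols(3 * H, 4 * H - 1) = (dc_new % i) % (1.0 - g % g);
    gW += x.t() * pre;
    gU += HP.slice(s).t() * pre;
    dh_next = (1.0 - M) % dh_total + pre * Uall.t();
    dc_next = dc_new % f + (1.0 - M) % dc_next;
  }
  return Rcpp::List::create(Rcpp::Named("gW") = gW, Rcpp::Named("gU") = gU);
}
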