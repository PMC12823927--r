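// LSTM time-loop kernels. The sequential recurrence over T timesteps is the
// one hot spot that vectorised R cannot express efficiently, so forward and
// backward-through-time run here; all other layers stay in R. The forward
// caches (gate activations, cell states, hidden sequence) stay on the C++
// heap behind an external pointer so they are never copied through R.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

struct LstmCache {
  mat X2;        // (n*T) x F inputs, row = i + t*n
  cube gates;    // n x 4H x T, gate order: input, forget, cell, output
  cube c_all;    // n x H x (T+1)
  cube h_seq;    // n x T x H (the R sequence layout)
  int n, Tn;
};

// [[Rcpp::export]]
Rcpp::List lstm_fwd_cpp(const arma::mat& X2, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::vec& b,
                        int n, int Tn, bool return_sequences) {
  const int H = Wh.n_cols / 4;
  Rcpp::XPtr<LstmCache> cache(new LstmCache(), true);
  cache->X2 = X2;
  cache->n = n;
  cache->Tn = Tn;
  mat Zx = X2 * Wx;
  Zx.each_row() += b.t();
  cache->gates.set_size(n, 4 * H, Tn);
  cache->c_all.zeros(n, H, Tn + 1);
  cache->h_seq.zeros(n, Tn, H);
  mat h(n, H, fill::zeros), cc(n, H, fill::zeros);
  for (int t = 0; t < Tn; ++t) {
    mat z = Zx.rows(t * n, (t + 1) * n - 1) + h * Wh;
    mat ig = 1.0 / (1.0 + exp(-z.cols(0, H - 1)));
    mat fg = 1.0 / (1.0 + exp(-z.cols(H, 2 * H - 1)));
    mat gg = tanh(z.cols(2 * H, 3 * H - 1));
    mat og = 1.0 / (1.0 + exp(-z.cols(3 * H, 4 * H - 1)));
    cc = fg % cc + ig % gg;
    h = og % tanh(cc);
    cache->gates.slice(t) = join_rows(ig, fg, gg, og);
    cache->c_all.slice(t + 1) = cc;
    for (int k = 0; k < H; ++k) cache->h_seq.slice(k).col(t) = h.col(k);
  }
  Rcpp::List out = Rcpp::List::create(Rcpp::Named("ptr") = cache);
  if (return_sequences) {
    out["out"] = cache->h_seq;
  } else {
    out["out"] = h;
  }
  return out;
}

// dout_seq: (n, T, H) upstream gradient when the layer returned the whole
// sequence, otherwise dout_last (n, H) on the final state only.
// [[Rcpp::export]]
Rcpp::List lstm_bwd_cpp(SEXP cache_ptr, const arma::mat& Wx,
                        const arma::mat& Wh, const arma::cube& dout_seq,
                        const arma::mat& dout_last, bool return_sequences) {
  Rcpp::XPtr<LstmCache> cache(cache_ptr);
  const int n = cache->n;
  const int Tn = cache->Tn;
  const int H = Wh.n_rows;
  mat dWh(size(Wh), fill::zeros);
  mat dz_all(n * Tn, 4 * H);
  mat dh_next(n, H, fill::zeros), dc_next(n, H, fill::zeros);
  for (int t = Tn - 1; t >= 0; --t) {
    mat dh = dh_next;
    if (return_sequences) {
      for (int k = 0; k < H; ++k) dh.col(k) += dout_seq.slice(k).col(t);
    } else if (t == Tn - 1) {
      dh += dout_last;
    }
    const mat& g = cache->gates.slice(t);
    mat ig = g.cols(0, H - 1), fg = g.cols(H, 2 * H - 1);
    mat gg = g.cols(2 * H, 3 * H - 1), og = g.cols(3 * H, 4 * H - 1);
    mat tc = tanh(cache->c_all.slice(t + 1));
    mat dc = dc_next + dh % og % (1.0 - tc % tc);
    mat dog = dh % tc;
    mat dig = dc % gg;
    mat dgg = dc % ig;
    mat dfg = dc % cache->c_all.slice(t);
    dc_next = dc % fg;
    mat dz = join_rows(dig % ig % (1.0 - ig),
                       dfg % fg % (1.0 - fg),
                       dgg % (1.0 - gg % gg),
                       dog % og % (1.0 - og));
    mat h_prev(n, H, fill::zeros);
    if (t > 0) {
      for (int k = 0; k < H; ++k) {
        h_prev.col(k) = cache->h_seq.slice(k).col(t - 1);
      }
    }
    dWh += h_prev.t() * dz;
    dz_all.rows(t * n, (t + 1) * n - 1) = dz;
    dh_next = dz * Wh.t();
  }
  return Rcpp::List::create(
      Rcpp::Named("dX2") = mat(dz_all * Wx.t()),
      Rcpp::Named("dWx") = mat(cache->X2.t() * dz_all),
      Rcpp::Named("dWh") = dWh,
      Rcpp::Named("db") = vec(sum(dz_all, 0).t()));
}
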