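#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Leaky-tanh echo-state update driven by a fixed input series.
// Row t of the result is the hidden state reached after input row t,
// i.e. r(t + dt) when row t holds x(t).
// [[Rcpp::export]]
arma::mat esn_drive(const arma::mat& Win, const arma::mat& A,
                    const arma::vec& b, double leak,
                    const arma::mat& X, const arma::vec& r0) {
  const arma::uword T = X.n_rows, n = Win.n_rows;
  if (Win.n_cols != X.n_cols) stop("input width does not match W_in");
  if (A.n_rows != n || A.n_cols != n || b.n_elem != n || r0.n_elem != n)
    stop("inconsistent reservoir dimensions");
  arma::mat R(T, n);
  arma::vec r = r0;
  for (arma::uword t = 0; t < T; ++t) {
    arma::vec z = Win * X.row(t).t() + A * r + b;
    r = (1.0 - leak) * r + leak * arma::tanh(z);
    if (!r.is_finite()) stop("non-finite reservoir state at step %d", (int)(t + 1));
    R.row(t) = r.t();
  }
  return R;
}

// Closed-loop multi-step forecast.  Each group owns one reservoir plus a
// linear readout predicting the state components in outIdx (1-based) as
// x(t) + Wout r(t+dt); all groups advance synchronously on the shared
// state and the full predicted state is fed back as the next input.
// [[Rcpp::export]]
List esn_forecast(List groups, double leak, const arma::vec& x0, int steps) {
  const int G = groups.size();
  std::vector<arma::mat> Win(G), A(G), Wout(G);
  std::vector<arma::vec> b(G), r(G);
  std::vector<arma::uvec> idx(G);
  for (int g = 0; g < G; ++g) {
    List gr = groups[g];
    Win[g]  = as<arma::mat>(gr["Win"]);
    A[g]    = as<arma::mat>(gr["A"]);
    b[g]    = as<arma::vec>(gr["b"]);
    Wout[g] = as<arma::mat>(gr["Wout"]);
    r[g]    = as<arma::vec>(gr["r"]);
    idx[g]  = as<arma::uvec>(gr["outIdx"]) - 1;
  }
  const arma::uword N = x0.n_elem;
  arma::mat out(std::max(steps, 0), N);
  arma::vec x = x0;
  bool diverged = false;
  int done = 0;
  for (int s = 0; s < steps; ++s) {
    arma::vec xnew = x;
    for (int g = 0; g < G; ++g) {
      arma::vec z = Win[g] * x + A[g] * r[g] + b[g];
      r[g] = (1.0 - leak) * r[g] + leak * arma::tanh(z);
      xnew.elem(idx[g]) = x.elem(idx[g]) + Wout[g] * r[g];
    }
    x = xnew;
    if (!x.is_finite()) { diverged = true; break; }
    out.row(s) = x.t();
    done = s + 1;
  }
  arma::mat kept = (done > 0) ? out.rows(0, done - 1) : arma::mat(0, N);
  return List::create(_["states"] = kept,
                      _["diverged"] = diverged,
                      _["steps"] = done);
}
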