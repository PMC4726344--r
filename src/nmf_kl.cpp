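// Multiplicative-update NMF minimizing the generalized Kullback-Leibler
// divergence D(V || WH) = sum v*log(v/wh) - v + wh (Lee & Seung updates,
// monotone non-increasing). W columns are signature profiles, H rows the
// exposures. The hot loop lives here because signature extraction runs
// this factorization hundreds of times per bootstrap analysis.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static const double EPS = 1e-12;

static double kl_div(const mat& V, const mat& WH) {
  double d = accu(WH) - accu(V);
  uvec nz = find(V > 0);
  vec v = V.elem(nz);
  vec wh = WH.elem(nz) + EPS;
  d += accu(v % log(v / wh));
  return d;
}

// [[Rcpp::export]]
Rcpp::List nmf_kl_engine(const arma::mat& V, arma::mat W, arma::mat H,
                         int max_iter, double tol, bool update_w) {
  mat WH = W * H;
  std::vector<double> objective;
  objective.reserve(256);
  double prev = kl_div(V, WH);
  objective.push_back(prev);
  bool converged = false;
  int it = 0;
  for (it = 1; it <= max_iter; ++it) {
    // H update
    mat R = V / (WH + EPS);
    H %= (W.t() * R);
    H.each_col() /= (sum(W, 0).t() + EPS);
    WH = W * H;
    if (update_w) {
      R = V / (WH + EPS);
      W %= (R * H.t());
      W.each_row() /= (sum(H, 1).t() + EPS);
      WH = W * H;
    }
    double cur = kl_div(V, WH);
    objective.push_back(cur);
    double rel = std::fabs(prev - cur) / std::max(std::fabs(prev), 1.0);
    prev = cur;
    if (rel < tol) { converged = true; break; }
  }
  return Rcpp::List::create(
    Rcpp::Named("w") = W,
    Rcpp::Named("h") = H,
    Rcpp::Named("objective") = objective,
    Rcpp::Named("iterations") = std::min(it, max_iter),
    Rcpp::Named("converged") = converged);
}
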