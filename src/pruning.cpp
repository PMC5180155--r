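// Felsenstein pruning likelihood for a k-state continuous-time Markov model.
// Transition matrices P(t) = exp(Q t) come from one eigendecomposition of Q
// per call (fast when the same generator is applied to many edges); if the
// eigenvector matrix is ill-conditioned (defective or near-defective Q) each
// edge falls back to arma::expmat (scaling-and-squaring).
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct EigCache {
  bool ok;
  arma::cx_vec eval;
  arma::cx_mat evec;
  arma::cx_mat evec_inv;
};

EigCache decompose(const arma::mat& Q) {
  EigCache ec;
  ec.ok = false;
  if (!arma::eig_gen(ec.eval, ec.evec, Q)) return ec;
  if (!arma::inv(ec.evec_inv, ec.evec)) return ec;
  // reconstruction check guards against near-defective generators
  arma::mat recon = arma::real(ec.evec * arma::diagmat(ec.eval) * ec.evec_inv);
  double qn = arma::norm(Q, "fro");
  double err = arma::norm(recon - Q, "fro");
  ec.ok = (err <= 1e-9 * std::max(1.0, qn));
  return ec;
}

arma::mat transition(const arma::mat& Q, const EigCache& ec, double t) {
  arma::mat P;
  if (ec.ok) {
    arma::cx_vec e = arma::exp(ec.eval * t);
    P = arma::real(ec.evec * arma::diagmat(e) * ec.evec_inv);
  } else {
    P = arma::expmat(Q * t);
  }
  // clamp tiny negative round-off and renormalize rows
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  arma::vec rs = arma::sum(P, 1);
  for (arma::uword i = 0; i < P.n_rows; ++i) {
    if (rs(i) > 0) P.row(i) /= rs(i);
  }
  return P;
}

}  // namespace

//' @noRd
// [[Rcpp::export]]
double cpp_prune_loglik(const arma::imat& edge, const arma::vec& edge_length,
                        int n_tip, int n_node, const arma::mat& tip_partials,
                        const arma::mat& Q, const arma::vec& root_freq) {
  const int k = Q.n_rows;
  const int n_total = n_tip + n_node;
  arma::mat partial(n_total, k, arma::fill::ones);
  partial.rows(0, n_tip - 1) = tip_partials;

  EigCache ec = decompose(Q);
  double log_scale = 0.0;

  // edges are in ape postorder: children are complete before their parent
  for (arma::uword i = 0; i < edge.n_rows; ++i) {
    const int par = edge(i, 0) - 1;
    const int ch = edge(i, 1) - 1;
    arma::mat P = transition(Q, ec, edge_length(i));
    arma::vec v = P * partial.row(ch).t();
    double m = v.max();
    if (!(m > 0.0) || !std::isfinite(m)) return R_NegInf;
    v /= m;
    log_scale += std::log(m);
    partial.row(par) %= v.t();
  }

  const int root = n_tip;  // ape convention: root is node n_tip + 1
  double lik = arma::dot(root_freq, partial.row(root).t());
  if (!(lik > 0.0) || !std::isfinite(lik)) return R_NegInf;
  return std::log(lik) + log_scale;
}

//' @noRd
// [[Rcpp::export]]
arma::mat cpp_transition_matrix(const arma::mat& Q, double t) {
  EigCache ec = decompose(Q);
  return transition(Q, ec, t);
}
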