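#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// Felsenstein pruning pass over a postorder edge list.
//
// child, parent : 1-based node indices (tips 1..ntip, root = ntip + 1)
// elen          : branch length per edge, same order
// tipL          : ntip x k matrix of tip conditional likelihoods
//                 (indicator rows for observed states, all-ones for ambiguous)
// Q             : k x k generator
//
// Partials are rescaled per edge to avoid underflow; the cumulated log scale
// factor must be added back to the root likelihood. When return_P is true the
// per-edge transition matrices expm(Q * t) are returned as well (needed for
// marginal posteriors and stochastic mapping).
// [[Rcpp::export]]
List mk_pruning_cpp(const arma::ivec& child, const arma::ivec& parent,
                    const arma::vec& elen, const arma::mat& tipL,
                    const arma::mat& Q, const int n_node,
                    const bool return_P) {
  const int ntip = tipL.n_rows;
  const int k = Q.n_cols;
  const int ntot = ntip + n_node;
  const int ne = child.n_elem;

  arma::mat L(ntot, k, arma::fill::ones);
  L.rows(0, ntip - 1) = tipL;
  double logscale = 0.0;
  List Plist(return_P ? ne : 0);

  // transition matrices: eigendecomposition of Q when well-conditioned
  // (one decomposition, cheap per-branch reconstruction), otherwise
  // scaling-and-squaring per branch
  arma::cx_vec eval;
  arma::cx_mat evec, evinv;
  bool use_eig = arma::eig_gen(eval, evec, Q);
  if (use_eig) {
    double c = arma::cond(evec);
    if (!std::isfinite(c) || c > 1e8) use_eig = false;
    else use_eig = arma::inv(evinv, evec);
  }

  for (int e = 0; e < ne; ++e) {
    const int c = child[e] - 1;
    const int p = parent[e] - 1;
    arma::mat P;
    if (use_eig) {
      P = arma::real(evec * arma::diagmat(arma::exp(eval * elen[e])) *
                     evinv);
      P.clamp(0.0, 1.0);
    } else {
      P = arma::expmat(Q * elen[e]);
    }
    if (return_P) Plist[e] = P;
    // v_s = sum_j P(s, j) * L_child(j)
    arma::rowvec v = L.row(c) * P.t();
    double s = v.max();
    if (s <= 0.0 || !std::isfinite(s)) s = 1e-300;
    v /= s;
    logscale += std::log(s);
    L.row(p) %= v;
  }

  return List::create(_["partials"] = L,
                      _["logscale"] = logscale,
                      _["P"] = Plist);
}
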