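// Felsenstein pruning for a k-state continuous-time Markov chain on a
// rooted tree, with per-branch transition matrices exp(Q * b). Transition
// matrices are built from one eigendecomposition of Q per call (Q is tiny);
// if the eigenvector matrix is ill-conditioned the code falls back to
// scaling-and-squaring (arma::expmat) per branch.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static bool branch_mats(const arma::mat& Q, const arma::vec& blen,
                        std::vector<arma::mat>& P) {
  arma::cx_vec eval;
  arma::cx_mat evec;
  if (!arma::eig_gen(eval, evec, Q)) return false;
  arma::cx_mat evinv;
  if (!arma::inv(evinv, evec)) return false;
  // reconstruction sanity check
  arma::mat recon = arma::real(evec * arma::diagmat(eval) * evinv);
  if (arma::abs(recon - Q).max() > 1e-8 * (1.0 + arma::abs(Q).max()))
    return false;
  const arma::uword n = blen.n_elem;
  P.resize(n);
  for (arma::uword e = 0; e < n; ++e) {
    arma::cx_mat Pe = evec * arma::diagmat(arma::exp(eval * blen[e])) * evinv;
    arma::mat Pr = arma::real(Pe);
    Pr.clamp(0.0, arma::datum::inf);
    P[e] = Pr;
  }
  return true;
}

// edge: 2-column matrix (parent, child) in postorder; tipstate: 1..k per tip
// (ape node numbering: tips 1..ntip, root = ntip + 1).
// root_rule: 0 = likelihood-weighted (FitzJohn), 1 = uniform, 2 = stationary.
// [[Rcpp::export]]
List ctmc_pruning_cpp(const arma::imat& edge, const arma::vec& blen,
                      int ntip, int nnode, const arma::ivec& tipstate,
                      const arma::mat& Q, int root_rule) {
  const int k = Q.n_rows;
  const int ntot = ntip + nnode;
  std::vector<arma::mat> P;
  if (!branch_mats(Q, blen, P)) {
    const arma::uword n = blen.n_elem;
    P.resize(n);
    for (arma::uword e = 0; e < n; ++e) {
      arma::mat Pe = arma::expmat(Q * blen[e]);
      Pe.clamp(0.0, arma::datum::inf);
      P[e] = Pe;
    }
  }
  arma::mat partial(k, ntot, arma::fill::ones);
  for (int i = 0; i < ntip; ++i) {
    partial.col(i).zeros();
    int s = tipstate[i];
    if (s < 1 || s > k) stop("tip state out of range");
    partial(s - 1, i) = 1.0;
  }
  double logscale = 0.0;
  for (arma::uword e = 0; e < edge.n_rows; ++e) {
    int parent = edge(e, 0) - 1;
    int child = edge(e, 1) - 1;
    arma::vec v = P[e] * partial.col(child);
    double m = v.max();
    if (m <= 0.0) return List::create(_["loglik"] = -1e300,
                                      _["rootp"] = NumericVector(k));
    v /= m;
    logscale += std::log(m);
    partial.col(parent) %= v;
  }
  arma::vec Lroot = partial.col(ntip);  // root = ntip + 1 (ape convention)
  double lsum = arma::accu(Lroot);
  if (lsum <= 0.0) return List::create(_["loglik"] = -1e300,
                                       _["rootp"] = NumericVector(k));
  double L;
  arma::vec w(k);
  if (root_rule == 0) {          // weight each root state by its likelihood
    w = Lroot / lsum;
    L = arma::dot(w, Lroot);
  } else if (root_rule == 1) {   // uniform
    w.fill(1.0 / k);
    L = lsum / k;
  } else {                       // stationary distribution of Q
    arma::mat A = Q.t();
    A.row(0).ones();
    arma::vec b(k, arma::fill::zeros);
    b[0] = 1.0;
    arma::vec pi;
    if (!arma::solve(pi, A, b)) { w.fill(1.0 / k); } else { w = pi; }
    w.clamp(0.0, arma::datum::inf);
    w /= arma::accu(w);
    L = arma::dot(w, Lroot);
  }
  if (L <= 0.0) return List::create(_["loglik"] = -1e300,
                                    _["rootp"] = NumericVector(k));
  arma::vec rootw = Lroot / lsum;
  return List::create(_["loglik"] = std::log(L) + logscale,
                      _["rootp"] = NumericVector(rootw.begin(), rootw.end()));
}
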