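// Felsenstein pruning likelihood for a K-state continuous-time Markov chain
// on a rooted tree. Hot path of the MCMC, hence compiled.
// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>

using namespace arma;

// P(t) = exp(Qt) for every edge. Eigendecomposition of Q is done once; if the
// reconstruction error suggests a defective/ill-conditioned generator we fall
// back to per-edge scaling-and-squaring.
static bool eig_setup(const mat& Q, cx_mat& V, cx_mat& Vinv, cx_vec& lam) {
  if (!eig_gen(lam, V, Q)) return false;
  cx_mat Vi;
  if (!inv(Vi, V)) return false;
  mat recon = real(V * diagmat(lam) * Vi);
  double scale = norm(Q, "fro");
  if (scale < 1e-300) scale = 1.0;
  if (norm(recon - Q, "fro") / scale > 1e-9) return false;
  Vinv = Vi;
  return true;
}

// edge: (n_edges x 2) parent/child node ids, 1-based, in postorder (children
// before parents, as ape's reorder(tree, "postorder")). Tip partials are the
// 0/1 ambiguity rows for tips 1..n_tip; internal nodes n_tip+1 .. n_tip+n_node.
// [[Rcpp::export]]
double mk_loglik_cpp(const arma::mat& Q,
                     const arma::imat& edge,
                     const arma::vec& elen,
                     const arma::mat& tip_partials,
                     const arma::vec& root_freq) {
  const uword K = Q.n_rows;
  const uword n_tip = tip_partials.n_rows;
  const uword n_edge = edge.n_rows;
  const uword n_all = n_tip + n_edge + 1 - n_tip; // root has no edge
  // total nodes = n_edge + 1 for a rooted tree
  mat part(n_edge + 1, K, fill::ones);
  part.rows(0, n_tip - 1) = tip_partials;

  cx_mat V, Vinv;
  cx_vec lam;
  bool use_eig = eig_setup(Q, V, Vinv, lam);

  double log_scale = 0.0;
  mat P(K, K);
  for (uword e = 0; e < n_edge; ++e) {
    const uword parent = (uword)edge(e, 0) - 1;
    const uword child = (uword)edge(e, 1) - 1;
    const double t = elen(e);
    if (t == 0.0) {
      P.eye(K, K);
    } else if (use_eig) {
      P = real(V * diagmat(exp(lam * t)) * Vinv);
    } else {
      P = expmat(Q * t);
    }
    rowvec contrib = part.row(child) * P.t(); // contrib_i = sum_j P_ij part_j
    part.row(parent) %= contrib;
    double mx = part.row(parent).max();
    if (mx < 1e-140 && mx > 0.0) {
      part.row(parent) /= mx;
      log_scale += std::log(mx);
    }
  }
  const uword root = (uword)edge(n_edge - 1, 0) - 1;
  double L = dot(part.row(root).t(), root_freq);
  (void)n_all;
  if (L <= 0.0) return R_NegInf;
  return std::log(L) + log_scale;
}
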