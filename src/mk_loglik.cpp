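// Pruning-algorithm likelihood for a k-state CTMC on a rooted tree.
// Transition probabilities P(t) = exp(Q t) come from one eigendecomposition
// of Q per call (P(t) = V exp(D t) V^-1), falling back to scaling-and-squaring
// (arma::expmat) per branch when V is ill-conditioned.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

namespace {

struct QDecomp {
  bool use_eig;
  cx_vec eigval;
  cx_mat V;
  cx_mat Vinv;
  mat Q;
};

QDecomp decompose(const mat& Q) {
  QDecomp d;
  d.Q = Q;
  d.use_eig = false;
  cx_vec eigval;
  cx_mat V;
  if (eig_gen(eigval, V, Q)) {
    double rc = rcond(V);
    if (std::isfinite(rc) && rc > 1e-10) {
      d.eigval = eigval;
      d.V = V;
      d.Vinv = inv(V);
      d.use_eig = true;
    }
  }
  return d;
}

mat pmat(const QDecomp& d, double t) {
  mat P;
  if (d.use_eig) {
    cx_mat Pc = d.V * diagmat(exp(d.eigval * t)) * d.Vinv;
    P = real(Pc);
  } else {
    P = expmat(d.Q * t);
  }
  // clamp eigendecomposition round-off; rows renormalized implicitly by scaling
  P.transform([](double x) { return x < 0.0 ? 0.0 : x; });
  return P;
}

} // namespace

// Transition-probability matrices exp(Q * t) for a vector of times.
// [[Rcpp::export]]
arma::cube cpp_pmats(const arma::mat& Q, const arma::vec& times) {
  QDecomp d = decompose(Q);
  cube out(Q.n_rows, Q.n_cols, times.n_elem);
  for (uword e = 0; e < times.n_elem; ++e) out.slice(e) = pmat(d, times(e));
  return out;
}

// Log-likelihood of tip data under Q.
// edge: 2-column matrix of 1-based (parent, child) node ids in postorder;
// lens: branch lengths matching edge rows; tipliks: k x ntips matrix of
// per-tip state likelihoods (tips are nodes 1..ntips); nnode: total nodes.
// [[Rcpp::export]]
double cpp_mk_loglik(const arma::imat& edge, const arma::vec& lens,
                     const arma::mat& tipliks, int nnode,
                     const arma::mat& Q, const arma::vec& prior) {
  const uword k = Q.n_rows;
  const uword ntip = tipliks.n_cols;
  QDecomp d = decompose(Q);

  mat L(k, nnode, fill::ones);
  L.cols(0, ntip - 1) = tipliks;
  vec logscale(nnode, fill::zeros);

  for (uword e = 0; e < edge.n_rows; ++e) {
    uword p = edge(e, 0) - 1;
    uword c = edge(e, 1) - 1;
    vec v;
    if (d.use_eig) {
      // P(t) L = V (exp(d t) o (V^-1 L)): two matrix-vector products
      cx_vec w = d.Vinv * cx_vec(L.col(c), vec(k, fill::zeros));
      w %= exp(d.eigval * lens(e));
      v = real(d.V * w);
      v.transform([](double x) { return x < 0.0 ? 0.0 : x; });
    } else {
      v = pmat(d, lens(e)) * L.col(c);
    }
    L.col(p) %= v;
    logscale(p) += logscale(c);
    double m = L.col(p).max();
    if (!(m > 0.0) || !std::isfinite(m)) return -datum::inf;
    L.col(p) /= m;
    logscale(p) += std::log(m);
  }
  uword root = edge(edge.n_rows - 1, 0) - 1;
  double lik = dot(prior, L.col(root));
  if (!(lik > 0.0) || !std::isfinite(lik)) return -datum::inf;
  return std::log(lik) + logscale(root);
}

// Per-node partial (downward) likelihoods with per-node log scale factors,
// for ancestral reconstruction and conditional node-state sampling.
// [[Rcpp::export]]
Rcpp::List cpp_mk_partials(const arma::imat& edge, const arma::vec& lens,
                           const arma::mat& tipliks, int nnode,
                           const arma::mat& Q) {
  const uword k = Q.n_rows;
  const uword ntip = tipliks.n_cols;
  QDecomp d = decompose(Q);

  mat L(k, nnode, fill::ones);
  L.cols(0, ntip - 1) = tipliks;
  vec logscale(nnode, fill::zeros);
  cube P(k, k, edge.n_rows);

  for (uword e = 0; e < edge.n_rows; ++e) {
    uword p = edge(e, 0) - 1;
    uword c = edge(e, 1) - 1;
    P.slice(e) = pmat(d, lens(e));
    vec v = P.slice(e) * L.col(c);
    L.col(p) %= v;
    logscale(p) += logscale(c);
    double m = L.col(p).max();
    if (m > 0.0 && std::isfinite(m)) {
      L.col(p) /= m;
      logscale(p) += std::log(m);
    }
  }
  return Rcpp::List::create(Rcpp::Named("partials") = L,
                            Rcpp::Named("logscale") = logscale,
                            Rcpp::Named("pmats") = P);
}
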