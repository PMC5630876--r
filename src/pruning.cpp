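// Felsenstein pruning over an arbitrary discrete state space (61 sense
// codons or 20 amino acids), with per-column scaling to avoid underflow.
// Transition probabilities come from spectral decompositions of the
// reversible generator: P(t) = A1 * diag(exp(lambda * t)) * A2, where
// A1 = D^{-1/2} U, A2 = U' D^{1/2}, D = diag(pi).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static arma::mat pmat(const arma::mat& A1, const arma::mat& A2,
                      const arma::vec& lam, double t) {
  arma::mat P = A1 * arma::diagmat(arma::exp(lam * t)) * A2;
  P.clamp(0.0, arma::datum::inf);  // clip tiny negative round-off
  return P;
}

struct PruneState {
  std::vector<arma::mat> cond;    // conditional likelihoods per node
  std::vector<arma::rowvec> logs; // per-pattern log scalers per node
  std::vector<bool> used;
  int nstate, npat;
  PruneState(int nnodes, int nstate_, int npat_)
      : cond(nnodes + 1), logs(nnodes + 1), used(nnodes + 1, false),
        nstate(nstate_), npat(npat_) {}
  void absorb(int p, const arma::mat& contrib, const arma::rowvec& ls) {
    if (!used[p]) {
      cond[p] = contrib;
      logs[p] = ls;
      used[p] = true;
    } else {
      cond[p] %= contrib;
      logs[p] += ls;
    }
    arma::rowvec m = arma::max(cond[p], 0);
    m.transform([](double v) { return v > 0.0 ? v : 1.0; });
    cond[p].each_row() /= m;
    logs[p] += arma::log(m);
  }
};

// contribution of edge (., child) given its P matrix
static void edge_contrib(const PruneState& st, int child, int ntip,
                         const IntegerMatrix& tips, const arma::mat& P,
                         arma::mat& contrib, arma::rowvec& ls) {
  int nstate = st.nstate, npat = st.npat;
  contrib.set_size(nstate, npat);
  if (child <= ntip) {
    arma::vec ones = arma::sum(P, 1);  // row sums (= 1): missing tip
    for (int j = 0; j < npat; ++j) {
      int s = tips(child - 1, j);
      if (s > 0)
        contrib.col(j) = P.col(s - 1);
      else
        contrib.col(j) = ones;
    }
    ls.zeros(npat);
  } else {
    contrib = P * st.cond[child];
    ls = st.logs[child];
  }
}

// [[Rcpp::export]]
NumericVector prune_loglik_cpp(IntegerMatrix edge, NumericVector elen,
                               IntegerVector sys, IntegerMatrix tips,
                               List A1s, List A2s, List lams,
                               NumericVector pi) {
  int nedge = edge.nrow();
  int ntip = tips.nrow();
  int npat = tips.ncol();
  arma::vec piv(pi.begin(), pi.size(), false);
  int nstate = piv.n_elem;
  int nnodes = 0;
  for (int e = 0; e < nedge; ++e)
    nnodes = std::max(nnodes, std::max(edge(e, 0), edge(e, 1)));
  PruneState st(nnodes, nstate, npat);
  arma::mat contrib;
  arma::rowvec ls;
  int root = edge(nedge - 1, 0);
  for (int e = 0; e < nedge; ++e) {
    int p = edge(e, 0), c = edge(e, 1);
    int k = sys[e] - 1;
    arma::mat A1 = as<arma::mat>(A1s[k]);
    arma::mat A2 = as<arma::mat>(A2s[k]);
    arma::vec lam = as<arma::vec>(lams[k]);
    arma::mat P = pmat(A1, A2, lam, elen[e]);
    edge_contrib(st, c, ntip, tips, P, contrib, ls);
    st.absorb(p, contrib, ls);
  }
  arma::rowvec lik = piv.t() * st.cond[root];
  arma::rowvec out = arma::log(lik) + st.logs[root];
  return NumericVector(out.begin(), out.end());
}

// Branch-site class pair: all edges use the background system; the
// foreground edge (which must be incident to the root) is propagated
// twice, once with the background and once with the foreground system.
// Returns a 2 x npat matrix of per-pattern log-likelihoods:
// row 0 = foreground edge under background omega, row 1 = under
// foreground omega. This halves the work for the four-class mixture,
// whose classes pair up as (0, 2a) and (1, 2b).
// [[Rcpp::export]]
NumericMatrix classpair_loglik_cpp(IntegerMatrix edge, NumericVector elen,
                                   int fg_row, IntegerMatrix tips,
                                   const arma::mat& A1b, const arma::mat& A2b,
                                   const arma::vec& lamb,
                                   const arma::mat& A1f, const arma::mat& A2f,
                                   const arma::vec& lamf,
                                   NumericVector pi) {
  int nedge = edge.nrow();
  int ntip = tips.nrow();
  int npat = tips.ncol();
  arma::vec piv(pi.begin(), pi.size(), false);
  int nstate = piv.n_elem;
  int nnodes = 0;
  for (int e = 0; e < nedge; ++e)
    nnodes = std::max(nnodes, std::max(edge(e, 0), edge(e, 1)));
  int root = edge(nedge - 1, 0);
  int fg = fg_row - 1;
  if (edge(fg, 0) != root)
    stop("foreground edge must be incident to the root (re-root first)");
  PruneState st(nnodes, nstate, npat);
  arma::mat contrib;
  arma::rowvec ls;
  for (int e = 0; e < nedge; ++e) {
    if (e == fg) continue;
    int c = edge(e, 1);
    arma::mat P = pmat(A1b, A2b, lamb, elen[e]);
    edge_contrib(st, c, ntip, tips, P, contrib, ls);
    st.absorb(edge(e, 0), contrib, ls);
  }
  int fgc = edge(fg, 1);
  double t = elen[fg];
  arma::mat base = st.used[root] ? st.cond[root]
                                 : arma::ones<arma::mat>(nstate, npat);
  arma::rowvec base_ls =
      st.used[root] ? st.logs[root] : arma::zeros<arma::rowvec>(npat);

  NumericMatrix out(2, npat);
  const arma::mat* A1v[2] = {&A1b, &A1f};
  const arma::mat* A2v[2] = {&A2b, &A2f};
  const arma::vec* lamv[2] = {&lamb, &lamf};
  for (int v = 0; v < 2; ++v) {
    arma::mat P = pmat(*A1v[v], *A2v[v], *lamv[v], t);
    edge_contrib(st, fgc, ntip, tips, P, contrib, ls);
    arma::rowvec lik = piv.t() * (base % contrib);
    arma::rowvec res = arma::log(lik) + base_ls + ls;
    for (int j = 0; j < npat; ++j) out(v, j) = res[j];
  }
  return out;
}
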