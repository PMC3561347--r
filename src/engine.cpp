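// 20-state reversible pruning likelihood and its analytic gradient.
//
// Node numbering follows ape: tips 1..ntip, root ntip+1, internals above.
// Edges must be supplied in postorder (every child's subtree complete
// before the edge to its parent is processed).  Partial likelihoods are
// max-rescaled per pattern at node completion; the gradient machinery uses
// per-edge flow matrices M_e = sum_p (w_p / d_p) f_p g_p^T in which the
// scale factors cancel, so no scale bookkeeping is needed there.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

static const int NS = 20;

// Tip partials: npat x NS indicator rows (all ones for state 0 = missing).
static void fill_tip(arma::mat &D, const arma::imat &tipStates, int tip) {
  const int npat = tipStates.n_cols;
  D.zeros(npat, NS);
  for (int p = 0; p < npat; ++p) {
    int s = tipStates(tip, p);
    if (s <= 0) D.row(p).ones();
    else D(p, s - 1) = 1.0;
  }
}

// Downward (post-order) pass.  On return: D holds per-node partials,
// logScale the accumulated per-pattern log scale of the root partial,
// C the per-edge child contributions (D_child * P_e^T, child scaled).
static void down_pass(const arma::imat &tipStates,
                      const arma::imat &edge, const arma::cube &P,
                      int nNodes, int root,
                      std::vector<arma::mat> &D, arma::vec &logScale,
                      arma::cube *C) {
  const int npat = tipStates.n_cols;
  const int ntip = tipStates.n_rows;
  const int E = edge.n_rows;
  D.assign(nNodes, arma::mat());
  std::vector<bool> init(nNodes, false);
  // last edge index per parent (for scaling at completion)
  std::vector<int> lastEdge(nNodes, -1);
  for (int e = 0; e < E; ++e) lastEdge[edge(e, 0) - 1] = e;
  logScale.zeros(npat);
  for (int tip = 0; tip < ntip; ++tip) {
    fill_tip(D[tip], tipStates, tip);
    init[tip] = true;
  }
  for (int e = 0; e < E; ++e) {
    const int u = edge(e, 0) - 1, v = edge(e, 1) - 1;
    arma::mat contrib = D[v] * P.slice(e).t();
    if (C) C->slice(e) = contrib;
    if (!init[u]) { D[u] = contrib; init[u] = true; }
    else D[u] %= contrib;
    if (e == lastEdge[u] && u != root - 1) {
      // rescale completed internal node (root handled at the final sum)
      arma::vec mx = arma::max(D[u], 1);
      for (int p = 0; p < npat; ++p) {
        double m = mx(p);
        if (m > 0 && m != 1.0) { D[u].row(p) /= m; logScale(p) += std::log(m); }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_loglik(const arma::imat &tipStates, const arma::vec &weights,
                const arma::imat &edge, const arma::cube &P,
                const arma::vec &pi, int nNodes, int root) {
  const int npat = tipStates.n_cols;
  std::vector<arma::mat> D;
  arma::vec logScale;
  down_pass(tipStates, edge, P, nNodes, root, D, logScale, nullptr);
  arma::vec L = D[root - 1] * pi;
  double ll = 0.0;
  arma::vec site(npat);
  for (int p = 0; p < npat; ++p) {
    site(p) = (L(p) > 0) ? std::log(L(p)) + logScale(p) : -arma::datum::inf;
    ll += weights(p) * site(p);
  }
  return List::create(_["loglik"] = ll, _["sitelik"] = site);
}

// Frechet-derivative factor: Phi_kl = (e^{lk t} - e^{ll t}) / (lk - ll),
// with the confluent limit t e^{lk t} on (near-)equal eigenvalues.
static arma::mat phi_matrix(const arma::vec &lambda, double t) {
  arma::mat Phi(NS, NS);
  arma::vec elt = arma::exp(lambda * t);
  for (int k = 0; k < NS; ++k)
    for (int l = 0; l < NS; ++l) {
      double d = lambda(k) - lambda(l);
      Phi(k, l) = (std::fabs(d) < 1e-9) ? t * elt(k) : (elt(k) - elt(l)) / d;
    }
  return Phi;
}

// Log-likelihood plus analytic gradient wrt branch lengths and (optionally)
// log-exchangeabilities.  Eigensystem: Q = V diag(lambda) Vinv (reversible,
// real).  theta entries: 1-based residue indices (ti, tj), current rho
// values and the normalization constant cscale of the *unnormalized*
// exchangeability scale (Q was divided by cscale when built).
// [[Rcpp::export]]
List cpp_loglik_grad(const arma::imat &tipStates, const arma::vec &weights,
                     const arma::imat &edge, const arma::vec &t,
                     const arma::mat &V, const arma::mat &Vinv,
                     const arma::vec &lambda, const arma::vec &pi,
                     int nNodes, int root,
                     const arma::ivec &ti, const arma::ivec &tj,
                     const arma::vec &rhoFree, double cscale,
                     bool gradTheta) {
  const int npat = tipStates.n_cols;
  const int E = edge.n_rows;
  const int nTheta = ti.n_elem;

  arma::cube P(NS, NS, E);
  for (int e = 0; e < E; ++e) {
    arma::mat Pe = V * arma::diagmat(arma::exp(lambda * t(e))) * Vinv;
    Pe.clamp(0.0, arma::datum::inf);
    P.slice(e) = Pe;
  }
  arma::mat Q = V * arma::diagmat(lambda) * Vinv;

  std::vector<arma::mat> D;
  arma::vec logScale;
  arma::cube C(npat, NS, E);
  down_pass(tipStates, edge, P, nNodes, root, D, logScale, &C);

  arma::vec L = D[root - 1] * pi;
  double ll = 0.0;
  for (int p = 0; p < npat; ++p)
    ll += weights(p) * ((L(p) > 0) ? std::log(L(p)) + logScale(p)
                                   : -arma::datum::inf);

  // children edge indices per parent, in postorder edge order
  std::vector<std::vector<int>> kids(nNodes);
  for (int e = 0; e < E; ++e) kids[edge(e, 0) - 1].push_back(e);

  // upward partials U (outside-subtree likelihood given the node's state)
  std::vector<arma::mat> U(nNodes);
  U[root - 1] = arma::repmat(pi.t(), npat, 1);

  arma::vec grad_t(E, arma::fill::zeros);
  arma::mat K(NS, NS, arma::fill::zeros);

  // process edges parent-first (reverse postorder)
  for (int e = E - 1; e >= 0; --e) {
    const int u = edge(e, 0) - 1, v = edge(e, 1) - 1;
    // sibling product via prefix/suffix over the parent's child edges
    const std::vector<int> &ke = kids[u];
    arma::mat sib(npat, NS, arma::fill::ones);
    for (int w : ke) if (w != e) sib %= C.slice(w);
    arma::mat F = U[u] % sib;                       // f_e, arbitrary scale
    arma::mat Uv = F * P.slice(e);                  // pre-scaled U_child
    // per-pattern denominator d_p = f P g = sum(Uv .* D_v)
    arma::vec d = arma::sum(Uv % D[v], 1);
    arma::vec r(npat);
    for (int p = 0; p < npat; ++p)
      r(p) = (d(p) > 0) ? weights(p) / d(p) : 0.0;
    arma::mat Fw = F.each_col() % r;
    arma::mat M = Fw.t() * D[v];                    // 20 x 20 flow matrix
    grad_t(e) = arma::accu((Q * P.slice(e)) % M);
    if (gradTheta) K += phi_matrix(lambda, t(e)) % (V.t() * M * Vinv.t());
    if (v >= (int)tipStates.n_rows) {               // internal child: store U
      arma::vec mx = arma::max(Uv, 1);
      for (int p = 0; p < npat; ++p)
        if (mx(p) > 0) Uv.row(p) /= mx(p);
      U[v] = Uv;
    }
  }

  arma::vec grad_theta;
  if (gradTheta && nTheta > 0) {
    arma::mat Z = Vinv.t() * K * V.t();
    double d0 = arma::dot(lambda, K.diag());
    grad_theta.set_size(nTheta);
    for (int m = 0; m < nTheta; ++m) {
      const int i = ti(m) - 1, j = tj(m) - 1;
      const double rm = rhoFree(m);
      double sparse = rm * (pi(j) * Z(i, j) + pi(i) * Z(j, i)
                            - pi(j) * Z(i, i) - pi(i) * Z(j, j)) / cscale;
      double sm = 2.0 * rm * pi(i) * pi(j) / cscale;
      grad_theta(m) = sparse - sm * d0;
    }
  }
  return List::create(_["loglik"] = ll, _["grad_t"] = grad_t,
                      _["grad_theta"] = grad_theta);
}
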