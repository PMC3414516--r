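// Felsenstein pruning for the GY94 codon model, with analytic
// branch-length derivatives via a combined down-pass/up-pass. The 61x61
// transition matrices are obtained by eigendecomposition of the
// pi^{1/2}-symmetrised generator (the chain is reversible).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static arma::mat build_Q(double kappa, double omega, const arma::vec& pi,
                         const arma::imat& single, const arma::imat& ti,
                         const arma::imat& ns) {
  const int n = pi.n_elem;
  arma::mat Q(n, n, arma::fill::zeros);
  for (int i = 0; i < n; ++i) {
    for (int j = 0; j < n; ++j) {
      if (single(i, j)) {
        double q = pi(j);
        if (ti(i, j)) q *= kappa;
        if (ns(i, j)) q *= omega;
        Q(i, j) = q;
      }
    }
  }
  Q.diag() = -arma::sum(Q, 1);
  double scale = -arma::dot(pi, Q.diag());
  Q /= scale;
  return Q;
}

struct EigQ {
  arma::vec eval;
  arma::mat evec;      // eigenvectors of the symmetrised generator
  arma::vec sqp, isqp; // sqrt(pi), 1/sqrt(pi)
  arma::mat Q;
  arma::mat P(double t) const {
    arma::mat E = evec * arma::diagmat(arma::exp(eval * t)) * evec.t();
    arma::mat out = arma::diagmat(isqp) * E * arma::diagmat(sqp);
    out.clamp(0.0, arma::datum::inf);
    return out;
  }
};

static EigQ eig_gy94(double kappa, double omega, const arma::vec& pi,
                     const arma::imat& single, const arma::imat& ti,
                     const arma::imat& ns) {
  EigQ e;
  e.Q = build_Q(kappa, omega, pi, single, ti, ns);
  e.sqp = arma::sqrt(pi);
  e.isqp = 1.0 / e.sqp;
  arma::mat B = arma::diagmat(e.sqp) * e.Q * arma::diagmat(e.isqp);
  B = (B + B.t()) / 2.0;
  arma::eig_sym(e.eval, e.evec, B);
  return e;
}

// tips: ntip x npat, 0-based codon states, -1 = ambiguous.
// edges: nedge x 2 (parent, child), 0-based, postorder (children first).
// edge_class: 0-based class index into omegas.
// [[Rcpp::export]]
List cpp_gy94_loglik(const arma::imat& tips, const arma::vec& weights,
                     const arma::imat& edges, const arma::vec& edge_len,
                     const arma::ivec& edge_class, double kappa,
                     const arma::vec& omegas, const arma::vec& pi,
                     const arma::imat& single, const arma::imat& ti,
                     const arma::imat& ns, bool want_grad = false) {
  const int nstate = pi.n_elem;
  const int ntip = tips.n_rows;
  const int npat = tips.n_cols;
  const int nedge = edges.n_rows;
  const int ntotal = nedge + 1;  // total nodes in a connected tree

  std::vector<EigQ> eq(omegas.n_elem);
  for (arma::uword c = 0; c < omegas.n_elem; ++c)
    eq[c] = eig_gy94(kappa, omegas(c), pi, single, ti, ns);

  std::vector<arma::mat> Pmat(nedge), M(nedge);
  std::vector<arma::mat> D(ntotal);
  std::vector<bool> has_D(ntotal, false);
  arma::vec logscale(npat, arma::fill::zeros);

  for (int e = 0; e < nedge; ++e) {
    int p = edges(e, 0), c = edges(e, 1);
    const EigQ& model = eq[edge_class(e)];
    Pmat[e] = model.P(edge_len(e));
    if (c < ntip) {
      arma::mat m(nstate, npat);
      for (int s = 0; s < npat; ++s) {
        int st = tips(c, s);
        if (st >= 0) m.col(s) = Pmat[e].col(st);
        else m.col(s).ones();
      }
      M[e] = std::move(m);
    } else {
      // child is internal: its D is complete (postorder); rescale it
      arma::rowvec mx = arma::max(D[c], 0);
      mx.transform([](double v) { return v > 0 ? v : 1.0; });
      D[c].each_row() /= mx;
      logscale += arma::log(mx).t();
      M[e] = Pmat[e] * D[c];
    }
    if (!has_D[p]) {
      D[p] = M[e];
      has_D[p] = true;
    } else {
      D[p] %= M[e];
    }
  }

  int root = edges(nedge - 1, 0);
  arma::rowvec mx = arma::max(D[root], 0);
  mx.transform([](double v) { return v > 0 ? v : 1.0; });
  D[root].each_row() /= mx;
  logscale += arma::log(mx).t();
  arma::rowvec site = pi.t() * D[root];
  double loglik = 0.0;
  for (int s = 0; s < npat; ++s)
    loglik += weights(s) * (std::log(site(s)) + logscale(s));

  if (!want_grad) return List::create(_["loglik"] = loglik);

  // Up-pass: per-edge outside partials; analytic d lnL / d t_e.
  std::vector<std::vector<int>> child_edges(ntotal);
  for (int e = 0; e < nedge; ++e) child_edges[edges(e, 0)].push_back(e);

  std::vector<arma::mat> U(ntotal);
  U[root] = arma::repmat(pi, 1, npat);
  arma::vec grad(nedge, arma::fill::zeros);

  for (int e = nedge - 1; e >= 0; --e) {
    int p = edges(e, 0), c = edges(e, 1);
    arma::mat Ue = U[p];
    for (int f : child_edges[p]) {
      if (f != e) Ue %= M[f];
    }
    arma::mat QM = eq[edge_class(e)].Q * M[e];
    double g = 0.0;
    for (int s = 0; s < npat; ++s) {
      double denom = arma::dot(Ue.col(s), M[e].col(s));
      double numer = arma::dot(Ue.col(s), QM.col(s));
      g += weights(s) * numer / denom;
    }
    grad(e) = g;
    if (c >= ntip) {
      U[c] = Pmat[e].t() * Ue;
      arma::rowvec um = arma::max(U[c], 0);
      um.transform([](double v) { return v > 0 ? v : 1.0; });
      U[c].each_row() /= um;
    }
  }

  return List::create(_["loglik"] = loglik, _["grad_t"] = grad);
}

// Transition matrix helper used by the simulator (kept in C++ so the
// sampler and the likelihood share one implementation).
// [[Rcpp::export]]
arma::mat cpp_gy94_pmat(double kappa, double omega, const arma::vec& pi,
                        const arma::imat& single, const arma::imat& ti,
                        const arma::imat& ns, double t) {
  EigQ e = eig_gy94(kappa, omega, pi, single, ti, ns);
  arma::mat P = e.P(t);
  P.each_col() /= arma::sum(P, 1);
  return P;
}
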