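// Coordinate-ascent sweep over predictors for the variational fit.
//
// For each predictor j the sweep forms the single-variable sufficient
// statistics (bhat_j, S_j = V / x_j'x_j) from the current expected
// residuals, computes the mixture posterior of b_j in closed form, and
// accumulates the quantities needed for the ELBO and the empirical Bayes
// updates of w0 and V.  Component factorizations depend on x_j'x_j only
// through S_j, so they are computed once per group of predictors sharing
// the same x_j'x_j (a single group when X is standardized).

#include <RcppArmadillo.h>
using namespace arma;

// [[Rcpp::depends(RcppArmadillo)]]

static const double LOG2PI = 1.837877066409345483560659472811;

struct GroupPrecomp {
  mat A;      // (K*r) x r, rows k*r..k*r+r-1 hold A_k = S0_k (S0_k + S)^{-1}
  mat Cinv;   // (K*r) x r, stacked (S0_k + S)^{-1}
  mat S1;     // (r*r) x K, column k = vec(S1_k), S1_k = A_k S
  vec ldC;    // K log-determinants of S0_k + S
};

// [[Rcpp::export(name = ".mr_mash_sweep")]]
Rcpp::List mr_mash_sweep(const arma::mat& X,
                         arma::mat Rbar,
                         arma::mat Mu,
                         const arma::vec& xtx,
                         const arma::uvec& grp,   // 1-based group index per j
                         const arma::vec& gxtx,   // representative xtx per group
                         const arma::cube& S0,    // r x r x K
                         const arma::vec& w0,
                         const arma::mat& V,
                         const arma::mat& Vinv,
                         double logdetV) {
  const uword n = X.n_rows, p = X.n_cols, r = V.n_rows, K = S0.n_slices;
  const uword G = gxtx.n_elem;
  (void) n;

  vec logw0(K);
  for (uword k = 0; k < K; k++)
    logw0(k) = (w0(k) > 0) ? std::log(w0(k)) : -datum::inf;

  std::vector<GroupPrecomp> pre(G);
  for (uword g = 0; g < G; g++) {
    mat S = V / gxtx(g);
    GroupPrecomp P;
    P.A.set_size(K * r, r);
    P.Cinv.set_size(K * r, r);
    P.S1.set_size(r * r, K);
    P.ldC.set_size(K);
    for (uword k = 0; k < K; k++) {
      mat C = S0.slice(k) + S;
      C = 0.5 * (C + C.t());
      mat L;
      if (!chol(L, C))
        Rcpp::stop("prior component %d: S0 + S is not positive definite",
                   (int) (k + 1));
      P.ldC(k) = 2.0 * accu(log(L.diag()));
      mat Ci = inv_sympd(C);
      Ci = 0.5 * (Ci + Ci.t());
      mat A = S0.slice(k) * Ci;
      mat S1 = A * S;
      S1 = 0.5 * (S1 + S1.t());
      P.A.rows(k * r, k * r + r - 1) = A;
      P.Cinv.rows(k * r, k * r + r - 1) = Ci;
      P.S1.col(k) = vectorise(S1);
    }
    pre[g] = P;
  }

  mat W1(p, K), Bhat(p, r), var_part(r, r, fill::zeros);
  vec w1sum(K, fill::zeros);
  double negKL = 0.0, max_delta = 0.0;

  for (uword j = 0; j < p; j++) {
    const GroupPrecomp& P = pre[grp(j) - 1];
    vec xj = X.col(j);
    rowvec muold = Mu.row(j);
    Rbar += xj * muold;
    vec bhat = (Rbar.t() * xj) / xtx(j);

    mat Mmat = reshape(P.A * bhat, r, K);       // posterior component means
    mat Cb = reshape(P.Cinv * bhat, r, K);
    rowvec q = sum(Cb.each_col() % bhat, 0);    // bhat' (S0_k+S)^{-1} bhat

    vec lw = logw0 - 0.5 * (r * LOG2PI + P.ldC + q.t());
    double m = lw.max();
    if (!std::isfinite(m))
      Rcpp::stop("predictor %d: all mixture-component log-weights are "
                 "non-finite", (int) (j + 1));
    vec w1 = exp(lw - m);
    double z = accu(w1);
    w1 /= z;
    double logZ = m + std::log(z);

    vec bbar = Mmat * w1;
    mat Ebb = reshape(P.S1 * w1, r, r) + Mmat * diagmat(w1) * Mmat.t();
    Ebb = 0.5 * (Ebb + Ebb.t());

    // -KL(q_j || prior) = logZ - E_q log N(bhat; b_j, S_j)
    mat Mj = bhat * bhat.t() - bhat * bbar.t() - bbar * bhat.t() + Ebb;
    double logdetS = logdetV - r * std::log(xtx(j));
    double eqg = -0.5 * (r * LOG2PI + logdetS + xtx(j) * accu(Vinv % Mj));
    negKL += logZ - eqg;

    var_part += xtx(j) * (Ebb - bbar * bbar.t());
    w1sum += w1;
    W1.row(j) = w1.t();
    Bhat.row(j) = bhat.t();

    rowvec bb = bbar.t();
    double d = abs(bb - muold).max();
    if (d > max_delta) max_delta = d;
    Mu.row(j) = bb;
    Rbar -= xj * bb;
  }

  var_part = 0.5 * (var_part + var_part.t());
  return Rcpp::List::create(
    Rcpp::Named("Mu") = Mu,
    Rcpp::Named("Rbar") = Rbar,
    Rcpp::Named("negKL") = negKL,
    Rcpp::Named("var_part") = var_part,
    Rcpp::Named("w1sum") = w1sum,
    Rcpp::Named("W1") = W1,
    Rcpp::Named("Bhat") = Bhat,
    Rcpp::Named("max_delta") = max_delta);
}
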