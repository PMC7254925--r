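// Full-information ML likelihood and analytic gradient for the
// three-instrument measurement error model, evaluated over missingness-
// pattern sufficient statistics.  Mirrors the pure-R fiml_core() /
// fiml_grad_theta() pair (kept as a cross-check); this version exists
// because bootstrap-heavy analyses need thousands of refits.

#define ARMA_WARN_LEVEL 0
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

// par: natural-scale parameters in optimizer order:
//   mu_T, beta_Q0, beta_F0, [mu_Q2..J, mu_F2..J, mu_M2..J if drift_free],
//   beta_Q1, beta_F1, sigma2_T, sigma2_r, sigma2_s, rho_rs,
//   sigma2_eps, sigma2_u, sigma2_v
// Pattern statistics arrive flattened (see flatten_patterns() on the R
// side): obs_all = concatenated 1-based observed-column indices,
// off = 0-based offsets into obs_all (length npat + 1), n_pat = group
// sizes, ybar_all = concatenated pattern means, S_all = concatenated
// column-major scatter matrices, soff = offsets into S_all.
// Returned gradient is on the *transformed* scale (log-variances,
// arctanh correlation), matching theta_names().
// [[Rcpp::export]]
List fiml_eval_cpp(NumericVector par_, int J, bool drift_free,
                   IntegerVector obs_all, IntegerVector off,
                   NumericVector n_pat, NumericVector ybar_all,
                   NumericVector S_all, IntegerVector soff,
                   bool want_grad) {
  arma::vec par(par_.begin(), par_.size());
  int i = 0;
  double mu_T = par(i++), bQ0 = par(i++), bF0 = par(i++);
  arma::vec muQ(J, arma::fill::zeros), muF(J, arma::fill::zeros),
            muM(J, arma::fill::zeros);
  if (drift_free) {
    for (int j = 1; j < J; j++) muQ(j) = par(i++);
    for (int j = 1; j < J; j++) muF(j) = par(i++);
    for (int j = 1; j < J; j++) muM(j) = par(i++);
  }
  double a = par(i++), b = par(i++);
  double s2T = par(i++), s2r = par(i++), s2s = par(i++), rho = par(i++);
  double s2e = par(i++), s2u = par(i++), s2v = par(i++);
  double srss = std::sqrt(s2r * s2s), crs = rho * srss;

  const int d = 3 * J;
  arma::vec mu(d);
  arma::mat Sig(d, d);
  for (int j = 0; j < J; j++) {
    mu(j)         = muQ(j) + bQ0 + a * mu_T;
    mu(J + j)     = muF(j) + bF0 + b * mu_T;
    mu(2 * J + j) = muM(j) + mu_T;
  }
  for (int j = 0; j < J; j++)
    for (int k = 0; k < J; k++) {
      Sig(j, k)             = a * a * s2T + s2r + (j == k ? s2e : 0.0);
      Sig(J + j, J + k)     = b * b * s2T + s2s + (j == k ? s2u : 0.0);
      Sig(2*J + j, 2*J + k) = s2T + (j == k ? s2v : 0.0);
      Sig(j, J + k)     = Sig(J + k, j)     = a * b * s2T + crs;
      Sig(j, 2*J + k)   = Sig(2*J + k, j)   = a * s2T;
      Sig(J + j, 2*J + k) = Sig(2*J + k, J + j) = b * s2T;
    }

  const double LOG2PI = std::log(2.0 * M_PI);
  double ll = 0.0;
  arma::vec gmu(d, arma::fill::zeros);
  arma::mat W(d, d, arma::fill::zeros);

  int npat = n_pat.size();
  for (int pi = 0; pi < npat; pi++) {
    int p0 = off[pi], p1 = off[pi + 1];
    int pdim = p1 - p0;
    arma::uvec obs(pdim);
    for (int j = 0; j < pdim; j++) obs(j) = obs_all[p0 + j] - 1;
    double n = n_pat[pi];
    arma::vec ybar(const_cast<double*>(&ybar_all[p0]), pdim, false);
    arma::mat S(const_cast<double*>(&S_all[soff[pi]]), pdim, pdim, false);

    arma::mat So = Sig.submat(obs, obs);
    arma::mat R;
    if (!So.is_finite() || !arma::chol(R, So))
      return List::create(_["loglik"] = R_NegInf);
    double logdet = 2.0 * arma::accu(arma::log(R.diag()));
    arma::mat Rinv = arma::inv(arma::trimatu(R));
    arma::mat P = Rinv * Rinv.t();

    arma::vec dvec = ybar - mu.elem(obs);
    arma::vec Pd = P * dvec;
    double quad = arma::dot(dvec, Pd);
    ll += -0.5 * (n * obs.n_elem * LOG2PI + n * logdet +
                  arma::accu(P % S) + n * quad);
    if (want_grad) {
      gmu.elem(obs) += n * Pd;
      arma::mat A = S + n * (dvec * dvec.t());
      W.submat(obs, obs) += 0.5 * (P * A * P - n * P);
    }
  }
  if (!want_grad) return List::create(_["loglik"] = ll);

  arma::span Qi(0, J - 1), Fi(J, 2 * J - 1), Mi(2 * J, 3 * J - 1);
  double TQQ = arma::accu(W(Qi, Qi)), TFF = arma::accu(W(Fi, Fi)),
         TMM = arma::accu(W(Mi, Mi));
  double TQF = 2.0 * arma::accu(W(Qi, Fi)),
         TQM = 2.0 * arma::accu(W(Qi, Mi)),
         TFM = 2.0 * arma::accu(W(Fi, Mi));
  arma::vec dg = W.diag();
  double DQ = arma::accu(dg.subvec(0, J - 1)),
         DF = arma::accu(dg.subvec(J, 2 * J - 1)),
         DM = arma::accu(dg.subvec(2 * J, 3 * J - 1));
  double gQ = arma::accu(gmu.subvec(0, J - 1)),
         gF = arma::accu(gmu.subvec(J, 2 * J - 1)),
         gM = arma::accu(gmu.subvec(2 * J, 3 * J - 1));

  arma::vec g(par_.size());
  i = 0;
  g(i++) = a * gQ + b * gF + gM;  // mu_T
  g(i++) = gQ;                    // beta_Q0
  g(i++) = gF;                    // beta_F0
  if (drift_free) {
    for (int j = 1; j < J; j++) g(i++) = gmu(j);
    for (int j = 1; j < J; j++) g(i++) = gmu(J + j);
    for (int j = 1; j < J; j++) g(i++) = gmu(2 * J + j);
  }
  g(i++) = 2*a*s2T*TQQ + b*s2T*TQF + s2T*TQM + mu_T * gQ;  // beta_Q1
  g(i++) = 2*b*s2T*TFF + a*s2T*TQF + s2T*TFM + mu_T * gF;  // beta_F1
  g(i++) = s2T * (a*a*TQQ + b*b*TFF + TMM + a*b*TQF + a*TQM + b*TFM);
  g(i++) = s2r * TQQ + 0.5 * crs * TQF;   // d / d log sigma2_r
  g(i++) = s2s * TFF + 0.5 * crs * TQF;   // d / d log sigma2_s
  g(i++) = (1.0 - rho * rho) * srss * TQF; // d / d atanh rho
  g(i++) = s2e * DQ;
  g(i++) = s2u * DF;
  g(i++) = s2v * DM;

  return List::create(_["loglik"] = ll,
                      _["grad"] = NumericVector(g.begin(), g.end()));
}
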