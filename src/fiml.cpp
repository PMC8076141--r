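// FIML likelihood for conditional-MIMIC Gaussian models.
//
// The observed-data log-likelihood is accumulated over missingness patterns
// using per-pattern sufficient statistics (Sxx, Sxy, Syy over the pattern's
// observed indicator subset), so a likelihood evaluation costs O(#patterns)
// matrix work independent of the number of records.  Gradients and Hessians
// are central finite differences taken inside C++ to avoid call overhead.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

constexpr double LOG2PI = 1.8378770664093454836;
constexpr double PENALTY = -1e12; // surrogate for -Inf at inadmissible parameters

struct Pattern {
  arma::uvec obs;   // 0-based indicator indices observed in this pattern
  double n;         // number of records
  arma::mat Sxx;    // (q+1) x (q+1), sum of xtilde xtilde'
  arma::mat Sxy;    // (q+1) x p_o,  sum of xtilde y_o'
  arma::mat Syy;    // p_o x p_o,    sum of y_o y_o'
};

struct Model {
  int p, m, q;
  arma::mat Lambda0, Psi0, Gamma0, Kappa0, Theta0;
  arma::vec nu0;
  arma::imat free_tab; // nfree x 3: target, row, col (0-based)
};

Model parse_model(const List& model) {
  Model M;
  M.p = as<int>(model["p"]);
  M.m = as<int>(model["m"]);
  M.q = as<int>(model["q"]);
  M.Lambda0 = as<arma::mat>(model["Lambda0"]);
  M.Psi0    = as<arma::mat>(model["Psi0"]);
  M.Gamma0  = as<arma::mat>(model["Gamma0"]);
  M.Kappa0  = as<arma::mat>(model["Kappa0"]);
  M.Theta0  = as<arma::mat>(model["Theta0"]);
  M.nu0     = as<arma::vec>(model["nu0"]);
  M.free_tab = as<arma::imat>(model["free_tab"]);
  return M;
}

std::vector<Pattern> parse_patterns(const List& patterns) {
  std::vector<Pattern> out;
  out.reserve(patterns.size());
  for (int g = 0; g < patterns.size(); ++g) {
    List pg = patterns[g];
    Pattern P;
    P.obs = as<arma::uvec>(pg["obs"]);
    P.n   = as<double>(pg["n"]);
    P.Sxx = as<arma::mat>(pg["Sxx"]);
    P.Sxy = as<arma::mat>(pg["Sxy"]);
    P.Syy = as<arma::mat>(pg["Syy"]);
    out.push_back(std::move(P));
  }
  return out;
}

// Unpack a transformed free-parameter vector into model matrices.
// Targets: 0 Lambda, 1 Psi off-diagonal (Fisher-z), 2 Gamma, 3 Kappa,
//          4 nu, 5 Theta diagonal (log variance), 6 Theta off-diagonal.
void unpack(const Model& M, const arma::vec& theta,
            arma::mat& Lambda, arma::mat& Psi, arma::mat& Gamma,
            arma::mat& Kappa, arma::vec& nu, arma::mat& Theta) {
  Lambda = M.Lambda0; Psi = M.Psi0; Gamma = M.Gamma0;
  Kappa = M.Kappa0;  nu  = M.nu0;  Theta = M.Theta0;
  const int nf = M.free_tab.n_rows;
  for (int k = 0; k < nf; ++k) {
    const int tgt = M.free_tab(k, 0);
    const int i = M.free_tab(k, 1);
    const int j = M.free_tab(k, 2);
    const double v = theta(k);
    switch (tgt) {
      case 0: Lambda(i, j) = v; break;
      case 1: Psi(i, j) = Psi(j, i) = std::tanh(v); break;
      case 2: Gamma(i, j) = v; break;
      case 3: Kappa(i, j) = v; break;
      case 4: nu(i) = v; break;
      case 5: Theta(i, i) = std::exp(v); break;
      case 6: Theta(i, j) = Theta(j, i) = v; break;
    }
  }
}

double loglik_CSigma(const std::vector<Pattern>& pats,
                     const arma::mat& C, const arma::mat& Sigma) {
  double ll = 0.0;
  for (const Pattern& P : pats) {
    const arma::uword po = P.obs.n_elem;
    arma::mat Soo = Sigma.submat(P.obs, P.obs);
    arma::mat U;
    if (!arma::chol(U, Soo)) return NA_REAL;
    const double logdet = 2.0 * arma::accu(arma::log(U.diag()));
    arma::mat Co = C.rows(P.obs);                 // p_o x (q+1)
    arma::mat CS = Co * P.Sxy;                    // p_o x p_o
    arma::mat R = P.Syy - CS - CS.t() + Co * P.Sxx * Co.t();
    // trace(Soo^{-1} R) via the Cholesky factor
    arma::mat V, W;
    if (!arma::solve(V, arma::trimatl(U.t()), R,
                     arma::solve_opts::no_approx)) return NA_REAL;
    if (!arma::solve(W, arma::trimatu(U), V,
                     arma::solve_opts::no_approx)) return NA_REAL;
    ll += -0.5 * (P.n * (double)po * LOG2PI + P.n * logdet + arma::trace(W));
  }
  return ll;
}

// graded infeasibility penalty: worse the more negative the spectrum,
// so line searches retain a useful downhill direction
double pd_penalty(const arma::mat& S) {
  arma::vec ev;
  if (!arma::eig_sym(ev, S)) return PENALTY;
  return PENALTY * (1.0 + arma::accu(arma::abs(ev(arma::find(ev < 0)))));
}

double eval_ll(const Model& M, const std::vector<Pattern>& pats,
               const arma::vec& theta) {
  arma::mat Lambda, Psi, Gamma, Kappa, Theta;
  arma::vec nu;
  unpack(M, theta, Lambda, Psi, Gamma, Kappa, nu, Theta);
  arma::mat U;
  if (!arma::chol(U, Psi)) return pd_penalty(Psi);
  if (!arma::chol(U, Theta)) return pd_penalty(Theta);
  arma::mat C = arma::join_rows(nu, Lambda * Gamma + Kappa); // p x (q+1)
  arma::mat Sigma = Lambda * Psi * Lambda.t() + Theta;
  double ll = loglik_CSigma(pats, C, Sigma);
  if (!std::isfinite(ll)) return PENALTY;
  return ll;
}

// Analytic score of the FIML likelihood on the transformed parameter scale.
// Per pattern: d ll / d C_o = Soo^{-1} (Sxy' - C_o Sxx),
//             d ll / d Soo = -1/2 (n Soo^{-1} - Soo^{-1} R Soo^{-1}),
// accumulated into full-size mean/covariance gradients, then chained
// through C = [nu, Lambda Gamma + Kappa], Sigma = Lambda Psi Lambda' + Theta
// and the log/Fisher-z transforms.  Returns false at inadmissible points.
bool analytic_grad(const Model& M, const std::vector<Pattern>& pats,
                   const arma::vec& theta, arma::vec& g) {
  arma::mat Lambda, Psi, Gamma, Kappa, Theta;
  arma::vec nu;
  unpack(M, theta, Lambda, Psi, Gamma, Kappa, nu, Theta);
  arma::mat U;
  if (!arma::chol(U, Psi)) return false;
  if (!arma::chol(U, Theta)) return false;
  arma::mat C = arma::join_rows(nu, Lambda * Gamma + Kappa);
  arma::mat Sigma = Lambda * Psi * Lambda.t() + Theta;

  const int p = M.p, q1 = M.q + 1;
  arma::mat GC(p, q1, arma::fill::zeros);
  arma::mat GS(p, p, arma::fill::zeros);
  for (const Pattern& P : pats) {
    arma::mat Soo = Sigma.submat(P.obs, P.obs);
    arma::mat Ri;
    if (!arma::inv_sympd(Ri, Soo)) return false;
    arma::mat Co = C.rows(P.obs);
    arma::mat CS = Co * P.Sxy;
    arma::mat R = P.Syy - CS - CS.t() + Co * P.Sxx * Co.t();
    GC.rows(P.obs) += Ri * (P.Sxy.t() - Co * P.Sxx);
    GS.submat(P.obs, P.obs) += -0.5 * (P.n * Ri - Ri * R * Ri);
  }
  arma::vec Gnu = GC.col(0);
  arma::mat GA = GC.cols(1, q1 - 1);
  arma::mat GLambda = GA * Gamma.t() + 2.0 * GS * Lambda * Psi;
  arma::mat GGamma = Lambda.t() * GA;
  arma::mat GPsiFull = Lambda.t() * GS * Lambda;

  const int nf = M.free_tab.n_rows;
  g.set_size(nf);
  for (int k = 0; k < nf; ++k) {
    const int tgt = M.free_tab(k, 0);
    const int i = M.free_tab(k, 1);
    const int j = M.free_tab(k, 2);
    double v = 0.0;
    switch (tgt) {
      case 0: v = GLambda(i, j); break;
      case 1: v = 2.0 * GPsiFull(i, j) * (1.0 - Psi(i, j) * Psi(i, j));
              break;
      case 2: v = GGamma(i, j); break;
      case 3: v = GA(i, j); break;
      case 4: v = Gnu(i); break;
      case 5: v = GS(i, i) * Theta(i, i); break;
      case 6: v = 2.0 * GS(i, j); break;
    }
    g(k) = v;
  }
  return true;
}

} // namespace

// [[Rcpp::export]]
double fiml_loglik_cpp(List model, List patterns, NumericVector theta) {
  Model M = parse_model(model);
  std::vector<Pattern> pats = parse_patterns(patterns);
  return eval_ll(M, pats, as<arma::vec>(theta));
}

// [[Rcpp::export]]
double fiml_loglik_moments_cpp(List patterns, arma::mat C, arma::mat Sigma) {
  std::vector<Pattern> pats = parse_patterns(patterns);
  double ll = loglik_CSigma(pats, C, Sigma);
  return std::isfinite(ll) ? ll : NA_REAL;
}

namespace {
arma::vec numeric_grad(const Model& M, const std::vector<Pattern>& pats,
                       const arma::vec& th, double h) {
  const int k = th.n_elem;
  arma::vec g(k);
  for (int i = 0; i < k; ++i) {
    const double hi = h * std::max(1.0, std::abs(th(i)));
    arma::vec tp = th, tm = th;
    tp(i) += hi; tm(i) -= hi;
    g(i) = (eval_ll(M, pats, tp) - eval_ll(M, pats, tm)) / (2.0 * hi);
  }
  return g;
}
} // namespace

// [[Rcpp::export]]
arma::vec fiml_grad_cpp(List model, List patterns, NumericVector theta,
                        double h = 1e-5) {
  Model M = parse_model(model);
  std::vector<Pattern> pats = parse_patterns(patterns);
  arma::vec th = as<arma::vec>(theta);
  arma::vec g;
  if (analytic_grad(M, pats, th, g)) return g;
  // inadmissible point: finite differences of the graded penalty still
  // point back toward the admissible region
  return numeric_grad(M, pats, th, h);
}

// [[Rcpp::export]]
arma::vec fiml_grad_num_cpp(List model, List patterns, NumericVector theta,
                            double h = 1e-5) {
  Model M = parse_model(model);
  std::vector<Pattern> pats = parse_patterns(patterns);
  return numeric_grad(M, pats, as<arma::vec>(theta), h);
}

// Observed-information Hessian: central differences of the analytic score.
// [[Rcpp::export]]
arma::mat fiml_hess_cpp(List model, List patterns, NumericVector theta,
                        double h = 1e-5) {
  Model M = parse_model(model);
  std::vector<Pattern> pats = parse_patterns(patterns);
  arma::vec th = as<arma::vec>(theta);
  const int k = th.n_elem;
  arma::mat H(k, k);
  arma::vec gp, gm;
  for (int i = 0; i < k; ++i) {
    const double hi = h * std::max(1.0, std::abs(th(i)));
    arma::vec tp = th, tm = th;
    tp(i) += hi; tm(i) -= hi;
    if (!analytic_grad(M, pats, tp, gp)) gp = numeric_grad(M, pats, tp, h);
    if (!analytic_grad(M, pats, tm, gm)) gm = numeric_grad(M, pats, tm, h);
    H.col(i) = (gp - gm) / (2.0 * hi);
  }
  return 0.5 * (H + H.t());
}
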