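// Numerical core: matrix exponentials for the continuous-time Markov model,
// the panel-observed likelihood, and the Laplace-approximated marginal
// likelihood of the cumulative-probit mixed model.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// [[Rcpp::export]]
arma::mat cpp_ctmc_expm(const arma::mat& Q, double dt) {
  arma::mat P = arma::expmat(Q * dt);
  // clamp round-off negatives; anything below -1e-12 would indicate a bug upstream
  P.transform([](double v) { return v < 0.0 ? 0.0 : v; });
  return P;
}

static void fill_generator(arma::mat& Q,
                           const arma::ivec& from, const arma::ivec& to,
                           const arma::vec& logq, const arma::vec& beta,
                           double z) {
  Q.zeros();
  for (arma::uword k = 0; k < from.n_elem; ++k) {
    Q(from[k], to[k]) = std::exp(logq[k] + beta[k] * z);
  }
  Q.diag() = -arma::sum(Q, 1);
}

// Panel log-likelihood: sum over consecutive observation pairs of
// log P(t1 -> t1+dt)[s_from, s_to], Q adjusted per patient by a scalar
// covariate z through log-linear loadings beta. First observations are
// conditioned on. With knot >= 0 the chain is piecewise-homogeneous: all
// intensities are scaled by exp(log_scale) after the knot, and intervals
// spanning it use the product of the two epoch transition matrices.
// [[Rcpp::export]]
List cpp_panel_loglik(int nstate,
                      const arma::ivec& from, const arma::ivec& to,
                      const arma::vec& logq, const arma::vec& beta,
                      const arma::ivec& p_from, const arma::ivec& p_to,
                      const arma::vec& p_t1, const arma::vec& p_dt,
                      const arma::vec& p_z,
                      double knot, double log_scale) {
  arma::mat Q(nstate, nstate);
  double ll = 0.0;
  int bad = -1;
  double z_cur = NA_REAL;
  bool have_q = false;
  double scale = std::exp(log_scale);
  for (arma::uword i = 0; i < p_from.n_elem; ++i) {
    if (!have_q || p_z[i] != z_cur) {
      fill_generator(Q, from, to, logq, beta, p_z[i]);
      z_cur = p_z[i];
      have_q = true;
    }
    arma::mat P;
    double a = p_t1[i], b = p_t1[i] + p_dt[i];
    if (knot < 0.0 || b <= knot) {
      P = arma::expmat(Q * p_dt[i]);
    } else if (a >= knot) {
      P = arma::expmat(Q * (scale * p_dt[i]));
    } else {
      P = arma::expmat(Q * (knot - a)) * arma::expmat(Q * (scale * (b - knot)));
    }
    double pr = P(p_from[i], p_to[i]);
    if (!(pr > 0.0) || !std::isfinite(pr)) {
      bad = static_cast<int>(i) + 1;  // 1-based index of offending pair
      ll = -std::numeric_limits<double>::infinity();
      break;
    }
    ll += std::log(pr);
  }
  return List::create(_["loglik"] = ll, _["bad_pair"] = bad);
}

// ---- cumulative-probit mixed model (Laplace) ----

// log P(y | u) for ordinal probit with thresholds tau (length ncat-1),
// u the latent mean; also first/second derivatives w.r.t. u.
static inline void probit_cell(const arma::vec& tau, int y, double u,
                               double& lp, double& g, double& h) {
  const double NEG = -1e10;
  int ncat = static_cast<int>(tau.n_elem) + 1;
  double a = (y < ncat) ? tau[y - 1] - u : arma::datum::inf;   // upper bound
  double c = (y > 1) ? tau[y - 2] - u : -arma::datum::inf;     // lower bound
  double Pa = (y < ncat) ? R::pnorm(a, 0.0, 1.0, 1, 0) : 1.0;
  double Pc = (y > 1) ? R::pnorm(c, 0.0, 1.0, 1, 0) : 0.0;
  double P = Pa - Pc;
  double da = (y < ncat) ? R::dnorm(a, 0.0, 1.0, 0) : 0.0;
  double dc = (y > 1) ? R::dnorm(c, 0.0, 1.0, 0) : 0.0;
  if (P < 1e-300) {
    lp = NEG;
    // push u back toward the observed cell
    g = (dc - da >= 0.0) ? 1e2 : -1e2;
    h = -1e2;
    return;
  }
  lp = std::log(P);
  g = (dc - da) / P;
  double term = ((y > 1 ? c * dc : 0.0) - (y < ncat ? a * da : 0.0)) / P;
  h = term - g * g;
  if (h > -1e-10) h = -1e-10;  // log-concave in u; guard round-off
}

// Laplace-approximated negative marginal log-likelihood of the cumulative
// probit model with per-patient (intercept, slope, quadratic) random effects,
// diagonal covariance. eta = fixed-effect linear predictor per observation,
// zt = scaled observation time, y in 1..ncat, patients delimited by
// start/len (0-based starts).
// [[Rcpp::export]]
List cpp_clmm_laplace(const arma::vec& eta, const arma::vec& zt,
                      const arma::ivec& y,
                      const arma::ivec& start, const arma::ivec& len,
                      const arma::vec& tau, const arma::vec& logsd,
                      bool want_modes) {
  int n = start.n_elem;
  arma::vec d = arma::exp(2.0 * logsd);       // RE variances
  arma::vec dinv = 1.0 / d;
  double logdetD = arma::accu(2.0 * logsd);
  double total = 0.0;
  arma::mat modes(want_modes ? n : 0, 3);
  arma::mat covs(want_modes ? n : 0, 9);
  arma::mat Dinv = arma::diagmat(dinv);

  for (int i = 0; i < n; ++i) {
    int s = start[i], m = len[i];
    arma::vec b(3, arma::fill::zeros);
    double obj = 0.0;
    arma::vec grad(3);
    arma::mat H(3, 3);
    // joint log-density and derivatives at b
    auto eval = [&](const arma::vec& bb, arma::vec& g, arma::mat& Hn) {
      double ll = 0.0;
      g.zeros(); Hn = Dinv;
      for (int j = 0; j < m; ++j) {
        double t = zt[s + j];
        arma::vec zrow = {1.0, t, t * t};
        double u = eta[s + j] + arma::dot(zrow, bb);
        double lp, gu, hu;
        probit_cell(tau, y[s + j], u, lp, gu, hu);
        ll += lp;
        g += gu * zrow;
        Hn += (-hu) * zrow * zrow.t();
      }
      g -= Dinv * bb;
      return ll - 0.5 * arma::dot(bb, Dinv * bb);
    };
    obj = eval(b, grad, H);
    for (int it = 0; it < 60; ++it) {
      arma::vec step = arma::solve(H, grad, arma::solve_opts::likely_sympd);
      double stepsz = 1.0;
      arma::vec gnew(3); arma::mat Hnew(3, 3);
      double objnew = -arma::datum::inf;
      arma::vec bnew;
      for (int hlf = 0; hlf < 30; ++hlf) {
        bnew = b + stepsz * step;
        objnew = eval(bnew, gnew, Hnew);
        if (objnew >= obj - 1e-12) break;
        stepsz *= 0.5;
      }
      if (!(objnew > -arma::datum::inf)) break;
      b = bnew; obj = objnew; grad = gnew; H = Hnew;
      if (arma::norm(grad) < 1e-8) break;
    }
    double ldH, sgn;
    arma::log_det(ldH, sgn, H);
    total += obj - 0.5 * logdetD - 0.5 * ldH;
    if (want_modes) {
      modes.row(i) = b.t();
      arma::mat S = arma::inv_sympd(H);
      covs.row(i) = arma::vectorise(S).t();
    }
  }
  if (want_modes)
    return List::create(_["nll"] = -total, _["modes"] = modes, _["covs"] = covs);
  return List::create(_["nll"] = -total);
}
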