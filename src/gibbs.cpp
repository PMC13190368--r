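// Blocked conjugate Gibbs sampler for the cross-classified and two-level
// AIG measurement models.
//
//   Y_sir = mu_r + lam_r * eta_s + alpha_sr + beta_ir + gamma_sir
//
// lam_ref = 1 and alpha_{s,ref} = 0 by identification; beta exists only under
// cross-classified sampling. All full conditionals are conjugate: normals for
// mu, free lam, eta, beta; multivariate normal for the per-subject alpha
// block; inverse gamma for the scalar variances; inverse Wishart for the
// alpha covariance. Uses R's RNG throughout so set.seed() in R gives
// bit-identical chains.

#include <RcppArmadillo.h>
using namespace Rcpp;

static double rinvgamma(double shape, double rate) {
  // X ~ Gamma(shape, rate)  =>  1/X ~ InvGamma(shape, rate)
  double g = R::rgamma(shape, 1.0 / rate);
  if (g <= 0 || !std::isfinite(g)) g = std::numeric_limits<double>::min();
  return 1.0 / g;
}

// Wishart(df, S) via Bartlett decomposition, S = LL^T (L lower Cholesky)
static arma::mat rwishart(double df, const arma::mat& S) {
  const int q = S.n_rows;
  arma::mat L = arma::chol(S, "lower");
  arma::mat A(q, q, arma::fill::zeros);
  for (int i = 0; i < q; ++i) {
    A(i, i) = std::sqrt(R::rchisq(df - i));
    for (int j = 0; j < i; ++j) A(i, j) = R::norm_rand();
  }
  arma::mat LA = L * A;
  return LA * LA.t();
}

// [[Rcpp::export(name = ".gibbs_chain")]]
List gibbs_chain(const arma::vec& y,
                 const arma::ivec& sub,   // 0-based subject index
                 const arma::ivec& lev,   // 0-based level index
                 const arma::ivec& inc,   // 0-based incidental index (cross)
                 const arma::ivec& inc_lev, // level of each incidental
                 int N, int R, int I_tot,
                 bool cross, int ref,     // 0-based reference level
                 List prior,
                 List init,
                 int n_iter, int n_warmup, int thin,
                 bool fix_loadings, bool store_beta) {
  const int n = y.n_elem;
  const int q = R - 1;

  // map level -> position among non-reference levels (-1 for reference)
  arma::ivec nrpos(R); nrpos.fill(-1);
  {
    int k = 0;
    for (int r = 0; r < R; ++r) if (r != ref) nrpos[r] = k++;
  }

  const double mu_mean = prior["mu_mean"], mu_var = prior["mu_var"];
  const double lam_mean = prior["lam_mean"], lam_var = prior["lam_var"];
  const double a0 = prior["ig_shape"], b0 = prior["ig_scale"];
  const double nu0 = prior["iw_df"];
  arma::mat S0 = prior["iw_scale"];

  arma::vec mu = init["mu"];
  arma::vec lam = init["lam"];
  double var_eta = init["var_eta"];
  arma::vec var_beta = init["var_beta"];
  arma::vec var_gamma = init["var_gamma"];
  arma::mat Sigma_a = init["cov_alpha"];       // q x q
  arma::vec eta(N, arma::fill::zeros);
  arma::mat alpha(N, R, arma::fill::zeros);    // reference column stays 0
  arma::vec beta(std::max(I_tot, 1), arma::fill::zeros);

  const int n_keep = (n_iter - n_warmup) / thin;
  const int n_par = R + (fix_loadings ? 0 : q) + 1 + q * (q + 1) / 2 +
                    (cross ? R : 0) + R;
  arma::mat out(n_keep, n_par);
  arma::mat out_beta(store_beta && cross ? n_keep : 0, I_tot);
  int jitter_retries = 0;

  // per-level observation counts
  arma::vec n_lev(R, arma::fill::zeros);
  for (int k = 0; k < n; ++k) n_lev[lev[k]] += 1.0;

  int kept = 0;
  for (int it = 0; it < n_iter; ++it) {

    // ---- eta_s | . ------------------------------------------------------
    {
      arma::vec prec(N, arma::fill::zeros), m(N, arma::fill::zeros);
      for (int k = 0; k < n; ++k) {
        const int r = lev[k], s = sub[k];
        const double b = cross ? beta[inc[k]] : 0.0;
        const double resid = y[k] - mu[r] - alpha(s, r) - b;
        prec[s] += lam[r] * lam[r] / var_gamma[r];
        m[s] += lam[r] * resid / var_gamma[r];
      }
      for (int s = 0; s < N; ++s) {
        const double v = 1.0 / (prec[s] + 1.0 / var_eta);
        eta[s] = v * m[s] + std::sqrt(v) * R::norm_rand();
      }
    }

    // ---- alpha_s (q-variate) | . ----------------------------------------
    if (q > 0) {
      arma::mat bmat(N, q, arma::fill::zeros);
      arma::mat cnt(N, q, arma::fill::zeros);
      for (int k = 0; k < n; ++k) {
        const int r = lev[k];
        if (r == ref) continue;
        const int s = sub[k], j = nrpos[r];
        const double b = cross ? beta[inc[k]] : 0.0;
        const double resid = y[k] - mu[r] - lam[r] * eta[s] - b;
        bmat(s, j) += resid / var_gamma[r];
        cnt(s, j) += 1.0 / var_gamma[r];
      }
      arma::mat Sinv;
      if (!arma::inv_sympd(Sinv, Sigma_a)) {
        Sinv = arma::inv_sympd(Sigma_a + 1e-8 * arma::eye(q, q));
        ++jitter_retries;
      }
      for (int s = 0; s < N; ++s) {
        arma::mat P = Sinv;
        for (int j = 0; j < q; ++j) P(j, j) += cnt(s, j);
        arma::mat U = arma::chol(P);  // P = U^T U
        arma::vec mean = arma::solve(arma::trimatu(U),
                         arma::solve(arma::trimatl(U.t()), bmat.row(s).t()));
        arma::vec z(q);
        for (int j = 0; j < q; ++j) z[j] = R::norm_rand();
        arma::vec draw = mean + arma::solve(arma::trimatu(U), z);
        for (int j = 0; j < q; ++j) {
          int r = 0;
          for (int rr = 0; rr < R; ++rr) if (nrpos[rr] == j) r = rr;
          alpha(s, r) = draw[j];
        }
      }
    }

    // ---- beta_ir | . (cross-classified only) ----------------------------
    if (cross && I_tot > 0) {
      arma::vec ssum(I_tot, arma::fill::zeros), scnt(I_tot, arma::fill::zeros);
      for (int k = 0; k < n; ++k) {
        const int r = lev[k], s = sub[k], i = inc[k];
        const double resid = y[k] - mu[r] - lam[r] * eta[s] - alpha(s, r);
        ssum[i] += resid;
        scnt[i] += 1.0;
      }
      for (int i = 0; i < I_tot; ++i) {
        const int r = inc_lev[i];
        const double vb = std::max(var_beta[r], 1e-300);
        const double prec = scnt[i] / var_gamma[r] + 1.0 / vb;
        const double v = 1.0 / prec;
        beta[i] = v * (ssum[i] / var_gamma[r]) + std::sqrt(v) * R::norm_rand();
      }
    }

    // ---- mu_r | . -------------------------------------------------------
    {
      arma::vec ssum(R, arma::fill::zeros);
      for (int k = 0; k < n; ++k) {
        const int r = lev[k], s = sub[k];
        const double b = cross ? beta[inc[k]] : 0.0;
        ssum[r] += y[k] - lam[r] * eta[s] - alpha(s, r) - b;
      }
      for (int r = 0; r < R; ++r) {
        const double prec = n_lev[r] / var_gamma[r] + 1.0 / mu_var;
        const double v = 1.0 / prec;
        mu[r] = v * (ssum[r] / var_gamma[r] + mu_mean / mu_var) +
                std::sqrt(v) * R::norm_rand();
      }
    }

    // ---- free lam_r | . (regression on current eta) ---------------------
    if (!fix_loadings) {
      arma::vec sxx(R, arma::fill::zeros), sxy(R, arma::fill::zeros);
      for (int k = 0; k < n; ++k) {
        const int r = lev[k], s = sub[k];
        if (r == ref) continue;
        const double b = cross ? beta[inc[k]] : 0.0;
        const double resid = y[k] - mu[r] - alpha(s, r) - b;
        sxx[r] += eta[s] * eta[s];
        sxy[r] += eta[s] * resid;
      }
      for (int r = 0; r < R; ++r) {
        if (r == ref) continue;  // identification: lam_ref == 1, never updated
        const double prec = sxx[r] / var_gamma[r] + 1.0 / lam_var;
        const double v = 1.0 / prec;
        lam[r] = v * (sxy[r] / var_gamma[r] + lam_mean / lam_var) +
                 std::sqrt(v) * R::norm_rand();
      }
    }

    // ---- var_eta | eta --------------------------------------------------
    var_eta = rinvgamma(a0 + 0.5 * N, b0 + 0.5 * arma::dot(eta, eta));

    // ---- var_gamma_r | full residuals -----------------------------------
    {
      arma::vec sse(R, arma::fill::zeros);
      for (int k = 0; k < n; ++k) {
        const int r = lev[k], s = sub[k];
        const double b = cross ? beta[inc[k]] : 0.0;
        const double resid = y[k] - mu[r] - lam[r] * eta[s] - alpha(s, r) - b;
        sse[r] += resid * resid;
      }
      for (int r = 0; r < R; ++r)
        var_gamma[r] = rinvgamma(a0 + 0.5 * n_lev[r], b0 + 0.5 * sse[r]);
    }

    // ---- var_beta_r | beta ----------------------------------------------
    if (cross && I_tot > 0) {
      arma::vec ssb(R, arma::fill::zeros), nb(R, arma::fill::zeros);
      for (int i = 0; i < I_tot; ++i) {
        ssb[inc_lev[i]] += beta[i] * beta[i];
        nb[inc_lev[i]] += 1.0;
      }
      for (int r = 0; r < R; ++r)
        var_beta[r] = rinvgamma(a0 + 0.5 * nb[r], b0 + 0.5 * ssb[r]);
    }

    // ---- Sigma_alpha | alpha (inverse Wishart) --------------------------
    if (q > 0) {
      arma::mat A(N, q);
      for (int j = 0; j < q; ++j) {
        int r = 0;
        for (int rr = 0; rr < R; ++rr) if (nrpos[rr] == j) r = rr;
        A.col(j) = alpha.col(r);
      }
      arma::mat Sn = S0 + A.t() * A;
      arma::mat Sn_inv;
      if (!arma::inv_sympd(Sn_inv, Sn)) {
        Sn_inv = arma::inv_sympd(Sn + 1e-8 * arma::eye(q, q));
        ++jitter_retries;
      }
      arma::mat W = rwishart(nu0 + N, Sn_inv);
      if (!arma::inv_sympd(Sigma_a, W)) {
        Sigma_a = arma::inv_sympd(W + 1e-8 * arma::eye(q, q));
        ++jitter_retries;
      }
    }

    // ---- store ----------------------------------------------------------
    if (it >= n_warmup && ((it - n_warmup) % thin == 0) && kept < n_keep) {
      int c = 0;
      for (int r = 0; r < R; ++r) out(kept, c++) = mu[r];
      if (!fix_loadings)
        for (int r = 0; r < R; ++r) if (r != ref) out(kept, c++) = lam[r];
      out(kept, c++) = var_eta;
      for (int a = 0; a < q; ++a)
        for (int bcol = a; bcol < q; ++bcol) out(kept, c++) = Sigma_a(a, bcol);
      if (cross) for (int r = 0; r < R; ++r) out(kept, c++) = var_beta[r];
      for (int r = 0; r < R; ++r) out(kept, c++) = var_gamma[r];
      if (store_beta && cross)
        for (int i = 0; i < I_tot; ++i) out_beta(kept, i) = beta[i];
      ++kept;
    }
  }

  return List::create(_["pars"] = out,
                      _["beta"] = out_beta,
                      _["jitter_retries"] = jitter_retries);
}
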