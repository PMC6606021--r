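// Marginal log-likelihood (and analytic gradient / per-subject scores) of
// the two-part latent growth curve model.
//
// Latent factors are ordered discrete block first (slope/quadratic before
// the intercept) then continuous block (intercept first), and Psi = L L'
// with L lower triangular. Writing eta_d = m_d + sqrt(2) L_dd z the
// continuous-part latents conditional on eta_d have mean shift
// B (eta_d - m_d) = sqrt(2) L_cd z and covariance L_cc L_cc', so the
// conditional covariance of the observed continuous indicators depends only
// on the missingness pattern and can be factorized once per pattern. The
// discrete-block integral is a prior-scaled Gauss-Hermite sum; all per-node
// quantities are kept node-major (K x .) so the inner work is small BLAS
// calls rather than scalar loops.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline double log1pexp_(double x) {
  if (x > 35.0) return x;
  if (x < -35.0) return std::exp(x);
  return std::log1p(std::exp(x));
}

// [[Rcpp::export]]
Rcpp::List cpp_tp_eval(const arma::vec& mu, const arma::mat& L,
                       const arma::vec& theta, const arma::vec& gamma,
                       int qd,
                       const arma::mat& Yb, const arma::mat& Yc,
                       const arma::mat& X, const arma::ivec& path,
                       const arma::mat& Lam_d, const arma::mat& Lam_c,
                       int link,
                       const arma::mat& Z, const arma::vec& W,
                       bool want_grad, bool want_scores = false) {
  const int n = Yb.n_rows;
  const int T = Yb.n_cols;
  const int q = mu.n_elem;
  const int qc = q - qd;
  const int K = Z.n_rows;
  const int p = X.n_cols;
  const double sqrt2 = std::sqrt(2.0);
  const double LOG2PI = std::log(2.0 * M_PI);
  const bool need_g = want_grad || want_scores;

  vec mu_d = (qd > 0) ? vec(mu.subvec(0, qd - 1)) : vec();
  vec mu_c = (qc > 0) ? vec(mu.subvec(qd, q - 1)) : vec();
  mat Ldd = (qd > 0) ? mat(L.submat(0, 0, qd - 1, qd - 1)) : mat();
  mat Lcd = (qc > 0 && qd > 0) ? mat(L.submat(qd, 0, q - 1, qd - 1))
                               : mat(qc, std::max(qd, 0), fill::zeros);
  mat Lcc = (qc > 0) ? mat(L.submat(qd, qd, q - 1, q - 1)) : mat();

  // per-subject latent mean offsets from covariate paths
  mat Od(n, std::max(qd, 1), fill::zeros);
  mat Oc(n, std::max(qc, 1), fill::zeros);
  bool any_d_path = false;
  for (int j = 0; j < p; ++j) {
    int f = path(j);
    if (f < qd) {
      any_d_path = true;
      Od.col(f) += gamma(j) * X.col(j);
    } else {
      Oc.col(f - qd) += gamma(j) * X.col(j);
    }
  }

  // discrete-part linear predictor at each node (node-major K x T)
  mat A0, logP0, log1mP0, P0;
  const bool pre_bern = (qd > 0) && !any_d_path;
  if (qd > 0) {
    mat U = sqrt2 * Z * Ldd.t();            // K x qd
    A0 = U * Lam_d.t();                     // K x T
    A0.each_row() += (Lam_d * mu_d).t();
    if (pre_bern) {
      logP0.set_size(K, T); log1mP0.set_size(K, T);
      if (need_g || link == 0) P0.set_size(K, T);
      for (int t = 0; t < T; ++t) for (int k = 0; k < K; ++k) {
        double a = A0(k, t);
        if (link == 0) {
          logP0(k, t) = -log1pexp_(-a);
          log1mP0(k, t) = -log1pexp_(a);
          P0(k, t) = 1.0 / (1.0 + std::exp(-a));
        } else {
          logP0(k, t) = R::pnorm(a, 0.0, 1.0, 1, 1);
          log1mP0(k, t) = R::pnorm(a, 0.0, 1.0, 0, 1);
        }
      }
    }
  }

  // continuous missingness patterns
  std::vector<uvec> pat_obs;
  ivec pat_id(n);
  {
    std::map<unsigned int, int> pat_map;
    for (int i = 0; i < n; ++i) {
      unsigned int key = 0;
      if (qc > 0) {
        for (int t = 0; t < T; ++t)
          if (std::isfinite(Yc(i, t))) key |= (1u << t);
      }
      auto it = pat_map.find(key);
      if (it == pat_map.end()) {
        int id = pat_obs.size();
        pat_map[key] = id;
        std::vector<uword> obs;
        for (int t = 0; t < T; ++t) if (key & (1u << t)) obs.push_back(t);
        pat_obs.push_back(uvec(obs));
        pat_id(i) = id;
      } else pat_id(i) = it->second;
    }
  }
  const int G = pat_obs.size();

  std::vector<mat> LamG(G), SigInvG(G), SIMG(G), LSIMG(G), GLG(G);
  std::vector<vec> qMG(G);
  std::vector<double> cstG(G, 0.0);
  mat Vt;  // qc x K : sqrt(2) L_cd Z'
  if (qc > 0 && qd > 0) Vt = sqrt2 * Lcd * Z.t();
  mat PsiCcond = (qc > 0) ? mat(Lcc * Lcc.t()) : mat();
  for (int g = 0; g < G; ++g) {
    const uvec& obs = pat_obs[g];
    const int m = obs.n_elem;
    if (m == 0 || qc == 0) continue;
    mat Lg = Lam_c.rows(obs);
    mat Sig = Lg * PsiCcond * Lg.t();
    for (int a = 0; a < m; ++a) Sig(a, a) += theta(obs(a));
    mat SigInv;
    if (!inv_sympd(SigInv, Sig)) {
      return Rcpp::List::create(Rcpp::Named("loglik") = R_NegInf,
                                Rcpp::Named("ok") = false);
    }
    double ld, sign;
    log_det(ld, sign, Sig);
    LamG[g] = Lg;
    SigInvG[g] = SigInv;
    cstG[g] = -0.5 * (m * LOG2PI + ld);
    mat M = (qd > 0) ? mat((Lg * Vt).t()) : mat(K, m, fill::zeros); // K x m
    SIMG[g] = M * SigInv;                  // K x m
    LSIMG[g] = SIMG[g] * Lg;               // K x qc
    qMG[g] = vec(sum(M % SIMG[g], 1));     // K
    GLG[g] = (Lg.t() * SigInv * Lg) * Lcc; // qc x qc
  }

  const vec logW = log(W);

  double loglik = 0.0;
  vec per_subject(n, fill::zeros);
  vec dmu(q, fill::zeros), dtheta(std::max(T, 1), fill::zeros),
      dgamma(std::max(p, 1), fill::zeros);
  mat dL(q, q, fill::zeros);
  const int n_Lfree = q * (q + 1) / 2;
  const int score_cols = q + n_Lfree + T + p;
  mat Scores;
  if (want_scores) Scores.zeros(n, score_cols);

  vec gk(K), bern(K), om(K);
  // per-subject natural-scale gradient pieces
  vec dmu_i(q), dtheta_i(std::max(T, 1)), dgamma_i(std::max(p, 1));
  mat dL_i(q, q);
  // per-subject work buffers, hoisted so repeated patterns reuse storage
  std::vector<int> dobs;
  vec ashift, robs, sr, lsr, wt, ws2, wb, mc;
  mat Cmat, Tmat, Tw, Smat, Lam_obs, Bmat;

  for (int i = 0; i < n; ++i) {
    bern.zeros();
    dobs.clear();
    if (qd > 0) {
      bool shift = any_d_path;
      if (shift) ashift = Lam_d * Od.row(i).t();
      for (int t = 0; t < T; ++t) {
        if (std::isfinite(Yb(i, t))) dobs.push_back(t);
      }
    }
    const int nb = dobs.size();
    // Cmat: K x nb score factors for the binary part
    if (need_g && nb > 0) Cmat.set_size(K, nb);
    for (int j = 0; j < nb; ++j) {
      int t = dobs[j];
      bool y1 = Yb(i, t) > 0.5;
      if (pre_bern) {
        bern += y1 ? logP0.col(t) : log1mP0.col(t);
        if (need_g) {
          if (link == 0) {
            Cmat.col(j) = (y1 ? 1.0 : 0.0) - P0.col(t);
          } else {
            for (int k = 0; k < K; ++k) {
              double a = A0(k, t);
              double ldn = R::dnorm(a, 0.0, 1.0, 1);
              Cmat(k, j) = y1 ? std::exp(ldn - logP0(k, t))
                              : -std::exp(ldn - log1mP0(k, t));
            }
          }
        }
      } else {
        double sh = any_d_path ? ashift(t) : 0.0;
        for (int k = 0; k < K; ++k) {
          double a = A0(k, t) + sh;
          if (link == 0) {
            double lp = -log1pexp_(-a), l1p = -log1pexp_(a);
            bern(k) += y1 ? lp : l1p;
            if (need_g) Cmat(k, j) = (y1 ? 1.0 : 0.0) - 1.0 / (1.0 + std::exp(-a));
          } else {
            double lp = R::pnorm(a, 0.0, 1.0, 1, 1);
            double l1p = R::pnorm(a, 0.0, 1.0, 0, 1);
            bern(k) += y1 ? lp : l1p;
            if (need_g) {
              double ldn = R::dnorm(a, 0.0, 1.0, 1);
              Cmat(k, j) = y1 ? std::exp(ldn - lp) : -std::exp(ldn - l1p);
            }
          }
        }
      }
    }

    // continuous part
    int g = pat_id(i);
    const uvec& obs = pat_obs[g];
    const int m = (qc > 0) ? (int)obs.n_elem : 0;
    double rSr = 0.0;
    if (m > 0) {
      mc = mu_c + Oc.row(i).t();
      robs.set_size(m);
      for (int a = 0; a < m; ++a) {
        robs(a) = Yc(i, obs(a)) - dot(LamG[g].row(a), mc);
      }
      sr = SigInvG[g] * robs;
      rSr = dot(robs, sr);
      lsr = LamG[g].t() * sr;
    }
    if (nb == 0 && m == 0) continue;

    gk = logW + bern;
    if (m > 0) {
      gk += cstG[g] - 0.5 * (rSr + qMG[g]);
      gk += SIMG[g] * robs;   // + r' SigInv M_k
    }
    double mx = gk.max();
    double ll_i = mx + std::log(accu(exp(gk - mx)));
    per_subject(i) = ll_i;
    loglik += ll_i;

    if (!need_g) continue;
    om = exp(gk - ll_i);   // posterior node weights, sum to 1

    dmu_i.zeros(); dtheta_i.zeros(); dgamma_i.zeros(); dL_i.zeros();

    if (m > 0) {
      // fused accumulation over nodes: Tmat(k,c) = lsr(c) - LSIMG[g](k,c);
      // wt = Tmat' om; A = (Tmat . om)' Z; TT = (Tmat . om)' Tmat;
      // ws2(a) = sum_k om_k (sr(a) - SIMG[g](k,a))^2
      const mat& LS = LSIMG[g];
      const mat& SI = SIMG[g];
      double wt_[3] = {0, 0, 0};
      double A_[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      double TT_[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      ws2.zeros(m);
      for (int k = 0; k < K; ++k) {
        const double o = om(k);
        double tv[3];
        for (int c = 0; c < qc; ++c) tv[c] = lsr(c) - LS(k, c);
        for (int c = 0; c < qc; ++c) {
          const double oc = o * tv[c];
          wt_[c] += oc;
          for (int d = 0; d < qd; ++d) A_[c][d] += oc * Z(k, d);
          for (int c2 = 0; c2 < qc; ++c2) TT_[c][c2] += oc * tv[c2];
        }
        for (int a = 0; a < m; ++a) {
          const double s = sr(a) - SI(k, a);
          ws2(a) += o * s * s;
        }
      }
      for (int c = 0; c < qc; ++c) {
        dmu_i(qd + c) = wt_[c];
        for (int d = 0; d < qd; ++d) dL_i(qd + c, d) = sqrt2 * A_[c][d];
        for (int c2 = 0; c2 <= c; ++c2) {
          double acc = 0.0;
          for (int c3 = 0; c3 < qc; ++c3) acc += TT_[c][c3] * Lcc(c3, c2);
          dL_i(qd + c, qd + c2) = -GLG[g](c, c2) + acc;
        }
      }
      for (int a = 0; a < m; ++a) {
        dtheta_i(obs(a)) = -0.5 * SigInvG[g](a, a) + 0.5 * ws2(a);
      }
      for (int j = 0; j < p; ++j) {
        int f = path(j);
        if (f >= qd) dgamma_i(j) = X(i, j) * wt_[f - qd];
      }
    }
    if (nb > 0) {
      // fused: Bmat = Cmat * Lam_obs; wb = Bmat' om;
      // dL_dd = sqrt2 (Bmat . om)' Z
      double wb_[3] = {0, 0, 0};
      double A2_[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
      for (int k = 0; k < K; ++k) {
        const double o = om(k);
        double bv[3];
        for (int d = 0; d < qd; ++d) {
          double acc = 0.0;
          for (int j = 0; j < nb; ++j) acc += Cmat(k, j) * Lam_d(dobs[j], d);
          bv[d] = acc;
          wb_[d] += o * acc;
        }
        for (int d = 0; d < qd; ++d) {
          const double ob = o * bv[d];
          for (int s = 0; s < qd; ++s) A2_[d][s] += ob * Z(k, s);
        }
      }
      for (int d = 0; d < qd; ++d) {
        dmu_i(d) = wb_[d];
        for (int s = 0; s <= d; ++s) dL_i(d, s) = sqrt2 * A2_[d][s];
      }
      for (int j = 0; j < p; ++j) {
        int f = path(j);
        if (f < qd) dgamma_i(j) += X(i, j) * wb_[f];
      }
    }

    if (want_grad) {
      dmu += dmu_i;
      dL += dL_i;
      if (T > 0) dtheta += dtheta_i;
      if (p > 0) dgamma += dgamma_i;
    }
    if (want_scores) {
      int c = 0;
      for (int f = 0; f < q; ++f) Scores(i, c++) = dmu_i(f);
      for (int s = 0; s < q; ++s) for (int r = s; r < q; ++r)
        Scores(i, c++) = dL_i(r, s);
      for (int t = 0; t < T; ++t) Scores(i, c++) = dtheta_i(t);
      for (int j = 0; j < p; ++j) Scores(i, c++) = dgamma_i(j);
    }
  }

  if (!need_g) {
    return Rcpp::List::create(Rcpp::Named("loglik") = loglik,
                              Rcpp::Named("per_subject") = per_subject,
                              Rcpp::Named("ok") = true);
  }
  dL = trimatl(dL);
  Rcpp::List out = Rcpp::List::create(
      Rcpp::Named("loglik") = loglik,
      Rcpp::Named("per_subject") = per_subject,
      Rcpp::Named("dmu") = dmu,
      Rcpp::Named("dL") = dL,
      Rcpp::Named("dtheta") = (T > 0) ? dtheta : vec(),
      Rcpp::Named("dgamma") = (p > 0) ? dgamma : vec(),
      Rcpp::Named("ok") = true);
  if (want_scores) out["scores"] = Scores;
  return out;
}
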