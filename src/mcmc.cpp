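// Metropolis-within-Gibbs sampler for the convolution (BYM-type) Poisson
// model with optional additive temporal terms:
//   Y_it ~ Poisson(E_it * exp(alpha + x_i' beta + u_i + eta_i + gamma_t + phi_t))
//   u iid N(0, 1/tau_u); eta intrinsic CAR; gamma iid N(0, 1/tau_gamma);
//   phi RW(1); flat prior on alpha; beta ~ N(0, beta_var);
//   Gamma(a, b) hyperpriors on the precisions (conjugate Gibbs draws).
// Single-site random-walk Metropolis with per-block proposal scales adapted
// toward 0.44 acceptance during burn-in only. eta and phi are recentred to
// sum to zero each sweep, the deducted means absorbed into alpha (an exactly
// measure-preserving move under the flat intercept prior when no region is
// an island; with islands the eta recentring is projection-only).
#include <Rcpp.h>
using namespace Rcpp;

static inline double clampd(double x, double lo, double hi) {
  return x < lo ? lo : (x > hi ? hi : x);
}

// [[Rcpp::export]]
List bym_mcmc_cpp(const NumericMatrix Y, const NumericMatrix E,
                  const NumericMatrix X, const List nb,
                  const IntegerVector deg, const IntegerMatrix edges,
                  const LogicalVector island, const int rank_eta,
                  const bool temporal,
                  const double beta_var, const double a_tau, const double b_tau,
                  const LogicalVector fix_tau, const NumericVector tau_init,
                  const int n_iter, const int n_burn, const int thin,
                  const bool lik_on, const List init, const int adapt_every) {
  const int n = Y.nrow(), T = Y.ncol(), p = X.ncol(), ne = edges.nrow();

  double alpha = as<double>(init["alpha"]);
  NumericVector beta = clone(as<NumericVector>(init["beta"]));
  NumericVector u = clone(as<NumericVector>(init["u"]));
  NumericVector eta = clone(as<NumericVector>(init["eta"]));
  NumericVector gam = clone(as<NumericVector>(init["gamma"]));
  NumericVector phi = clone(as<NumericVector>(init["phi"]));
  double tau_u = tau_init[0], tau_eta = tau_init[1];
  double tau_g = tau_init[2], tau_p = tau_init[3];

  std::vector<std::vector<int> > nbv(n);
  for (int i = 0; i < n; ++i) nbv[i] = as<std::vector<int> >(nb[i]);

  int n_noni = 0;
  for (int i = 0; i < n; ++i) if (!island[i]) ++n_noni;

  // cached linear-predictor pieces
  NumericVector xb(n, 0.0);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < p; ++j) xb[i] += X(i, j) * beta[j];
  NumericMatrix mu0(n, T);  // E * exp(linear predictor)
  if (lik_on) {
    for (int i = 0; i < n; ++i)
      for (int t = 0; t < T; ++t) {
        double lp = alpha + xb[i] + u[i] + eta[i];
        if (temporal) lp += gam[t] + phi[t];
        mu0(i, t) = E(i, t) * std::exp(lp);
      }
  }
  NumericVector Yrow(n, 0.0), Ycol(T, 0.0);
  double sumY = 0.0;
  for (int i = 0; i < n; ++i)
    for (int t = 0; t < T; ++t) {
      Yrow[i] += Y(i, t); Ycol[t] += Y(i, t); sumY += Y(i, t);
    }

  // proposal scales: u/eta/gamma/phi scales are relative to the current
  // conditional-prior sd, so mixing survives large precision swings
  double s_alpha = 0.1, s_u = 2.4, s_eta = 2.4, s_g = 2.4, s_p = 2.4;
  NumericVector s_beta(p > 0 ? p : 1, 0.1);
  // acceptance bookkeeping: [0]=alpha [1..p]=beta [p+1]=u [p+2]=eta
  // [p+3]=gamma [p+4]=phi [p+5]=gamma/phi swap
  const int nblk = p + 6;
  double s_sw = 2.4;
  std::vector<double> acc(nblk, 0.0), att(nblk, 0.0);
  std::vector<double> acc_all(nblk, 0.0), att_all(nblk, 0.0);

  const int n_keep = (n_iter - n_burn) / thin;
  int n_par = 1 + p + 2 + 2 * n;          // alpha, beta, tau_u, tau_eta, u, eta
  if (temporal) n_par += 2 + 2 * T;       // tau_gamma, tau_phi, gamma, phi
  NumericMatrix draws(n_keep, n_par);
  int keep_row = 0;

  for (int iter = 1; iter <= n_iter; ++iter) {
    // --- alpha (flat prior; skipped in prior-only runs, where it is
    //     unidentified and irrelevant) ---
    if (lik_on) {
      att[0] += 1.0; att_all[0] += 1.0;
      double d = s_alpha * norm_rand();
      double summu = 0.0;
      for (int i = 0; i < n; ++i)
        for (int t = 0; t < T; ++t) summu += mu0(i, t);
      double lr = sumY * d - (std::exp(d) - 1.0) * summu;
      if (std::log(unif_rand()) < lr) {
        alpha += d;
        double f = std::exp(d);
        for (int i = 0; i < n; ++i)
          for (int t = 0; t < T; ++t) mu0(i, t) *= f;
        acc[0] += 1.0; acc_all[0] += 1.0;
      }
    }

    // --- beta ---
    for (int j = 0; j < p; ++j) {
      att[1 + j] += 1.0; att_all[1 + j] += 1.0;
      double d = s_beta[j] * norm_rand();
      double bnew = beta[j] + d;
      double lr = -(bnew * bnew - beta[j] * beta[j]) / (2.0 * beta_var);
      if (lik_on) {
        for (int i = 0; i < n; ++i) {
          double di = d * X(i, j);
          double em1 = std::expm1(di);
          for (int t = 0; t < T; ++t)
            lr += Y(i, t) * di - mu0(i, t) * em1;
        }
      }
      if (std::log(unif_rand()) < lr) {
        beta[j] = bnew;
        if (lik_on) {
          for (int i = 0; i < n; ++i) {
            double f = std::exp(d * X(i, j));
            xb[i] += d * X(i, j);
            for (int t = 0; t < T; ++t) mu0(i, t) *= f;
          }
        } else {
          for (int i = 0; i < n; ++i) xb[i] += d * X(i, j);
        }
        acc[1 + j] += 1.0; acc_all[1 + j] += 1.0;
      }
    }

    // --- u (iid) ---
    {
      double sd_u = s_u / std::sqrt(tau_u);
      for (int i = 0; i < n; ++i) {
        att[p + 1] += 1.0; att_all[p + 1] += 1.0;
        double d = sd_u * norm_rand();
        double unew = u[i] + d;
        double lr = -0.5 * tau_u * (unew * unew - u[i] * u[i]);
        if (lik_on) {
          double em1 = std::expm1(d), murow = 0.0;
          for (int t = 0; t < T; ++t) murow += mu0(i, t);
          lr += Yrow[i] * d - murow * em1;
        }
        if (std::log(unif_rand()) < lr) {
          u[i] = unew;
          if (lik_on) {
            double f = std::exp(d);
            for (int t = 0; t < T; ++t) mu0(i, t) *= f;
          }
          acc[p + 1] += 1.0; acc_all[p + 1] += 1.0;
        }
      }
    }

    // --- eta (ICAR; islands pinned at 0) ---
    for (int i = 0; i < n; ++i) {
      if (island[i]) continue;
      att[p + 2] += 1.0; att_all[p + 2] += 1.0;
      double d = s_eta / std::sqrt(tau_eta * deg[i]) * norm_rand();
      double enew = eta[i] + d;
      double lr = 0.0;
      for (size_t k = 0; k < nbv[i].size(); ++k) {
        double ej = eta[nbv[i][k]];
        lr -= 0.5 * tau_eta * ((enew - ej) * (enew - ej) -
                               (eta[i] - ej) * (eta[i] - ej));
      }
      if (lik_on) {
        double em1 = std::expm1(d), murow = 0.0;
        for (int t = 0; t < T; ++t) murow += mu0(i, t);
        lr += Yrow[i] * d - murow * em1;
      }
      if (std::log(unif_rand()) < lr) {
        eta[i] = enew;
        if (lik_on) {
          double f = std::exp(d);
          for (int t = 0; t < T; ++t) mu0(i, t) *= f;
        }
        acc[p + 2] += 1.0; acc_all[p + 2] += 1.0;
      }
    }
    // recentre eta; absorb the mean into alpha when exact (no islands)
    if (n_noni > 0) {
      double m = 0.0;
      for (int i = 0; i < n; ++i) if (!island[i]) m += eta[i];
      m /= n_noni;
      for (int i = 0; i < n; ++i) if (!island[i]) eta[i] -= m;
      if (n_noni == n) {
        alpha += m;  // linear predictor unchanged: mu0 untouched
      } else if (lik_on) {
        double f = std::exp(-m);
        for (int i = 0; i < n; ++i)
          if (!island[i]) for (int t = 0; t < T; ++t) mu0(i, t) *= f;
      }
    }

    if (temporal) {
      // --- gamma (exchangeable) ---
      double sd_g = s_g / std::sqrt(tau_g);
      for (int t = 0; t < T; ++t) {
        att[p + 3] += 1.0; att_all[p + 3] += 1.0;
        double d = sd_g * norm_rand();
        double gnew = gam[t] + d;
        double lr = -0.5 * tau_g * (gnew * gnew - gam[t] * gam[t]);
        if (lik_on) {
          double em1 = std::expm1(d), mucol = 0.0;
          for (int i = 0; i < n; ++i) mucol += mu0(i, t);
          lr += Ycol[t] * d - mucol * em1;
        }
        if (std::log(unif_rand()) < lr) {
          gam[t] = gnew;
          if (lik_on) {
            double f = std::exp(d);
            for (int i = 0; i < n; ++i) mu0(i, t) *= f;
          }
          acc[p + 3] += 1.0; acc_all[p + 3] += 1.0;
        }
      }

      // --- phi (RW1) ---
      for (int t = 0; t < T; ++t) {
        att[p + 4] += 1.0; att_all[p + 4] += 1.0;
        double prec_t = (t == 0 || t == T - 1) ? 1.0 : 2.0;
        double d = s_p / std::sqrt(tau_p * prec_t) * norm_rand();
        double pnew = phi[t] + d;
        double lr = 0.0;
        if (t > 0) {
          double a0 = phi[t] - phi[t - 1], a1 = pnew - phi[t - 1];
          lr -= 0.5 * tau_p * (a1 * a1 - a0 * a0);
        }
        if (t < T - 1) {
          double a0 = phi[t + 1] - phi[t], a1 = phi[t + 1] - pnew;
          lr -= 0.5 * tau_p * (a1 * a1 - a0 * a0);
        }
        if (lik_on) {
          double em1 = std::expm1(d), mucol = 0.0;
          for (int i = 0; i < n; ++i) mucol += mu0(i, t);
          lr += Ycol[t] * d - mucol * em1;
        }
        if (std::log(unif_rand()) < lr) {
          phi[t] = pnew;
          if (lik_on) {
            double f = std::exp(d);
            for (int i = 0; i < n; ++i) mu0(i, t) *= f;
          }
          acc[p + 4] += 1.0; acc_all[p + 4] += 1.0;
        }
      }
      // --- gamma/phi swap: move mass between the unstructured and
      //     structured temporal terms without touching their sum; the
      //     likelihood cancels, so acceptance is the prior ratio alone.
      //     This mixes the split direction, which single-site updates
      //     traverse only slowly. ---
      for (int t = 0; t < T; ++t) {
        att[p + 5] += 1.0; att_all[p + 5] += 1.0;
        double prec_t = (t == 0 || t == T - 1) ? 1.0 : 2.0;
        double d = s_sw / std::sqrt(tau_g + tau_p * prec_t) * norm_rand();
        double gnew = gam[t] - d, pnew = phi[t] + d;
        double lr = -0.5 * tau_g * (gnew * gnew - gam[t] * gam[t]);
        if (t > 0) {
          double a0 = phi[t] - phi[t - 1], a1 = pnew - phi[t - 1];
          lr -= 0.5 * tau_p * (a1 * a1 - a0 * a0);
        }
        if (t < T - 1) {
          double a0 = phi[t + 1] - phi[t], a1 = phi[t + 1] - pnew;
          lr -= 0.5 * tau_p * (a1 * a1 - a0 * a0);
        }
        if (std::log(unif_rand()) < lr) {
          gam[t] = gnew;
          phi[t] = pnew;
          acc[p + 5] += 1.0; acc_all[p + 5] += 1.0;
        }
      }

      // recentre phi into alpha (global shift: predictor unchanged)
      double mp = 0.0;
      for (int t = 0; t < T; ++t) mp += phi[t];
      mp /= T;
      for (int t = 0; t < T; ++t) phi[t] -= mp;
      alpha += mp;
    }

    // --- precisions (conjugate Gamma full conditionals) ---
    if (!fix_tau[0]) {
      double q = 0.0;
      for (int i = 0; i < n; ++i) q += u[i] * u[i];
      tau_u = R::rgamma(a_tau + 0.5 * n, 1.0 / (b_tau + 0.5 * q));
    }
    if (!fix_tau[1]) {
      double q = 0.0;
      for (int e = 0; e < ne; ++e) {
        double dd = eta[edges(e, 0)] - eta[edges(e, 1)];
        q += dd * dd;
      }
      tau_eta = R::rgamma(a_tau + 0.5 * rank_eta, 1.0 / (b_tau + 0.5 * q));
    }
    if (temporal) {
      if (!fix_tau[2]) {
        double q = 0.0;
        for (int t = 0; t < T; ++t) q += gam[t] * gam[t];
        tau_g = R::rgamma(a_tau + 0.5 * T, 1.0 / (b_tau + 0.5 * q));
      }
      if (!fix_tau[3]) {
        double q = 0.0;
        for (int t = 1; t < T; ++t) {
          double dd = phi[t] - phi[t - 1];
          q += dd * dd;
        }
        tau_p = R::rgamma(a_tau + 0.5 * (T - 1), 1.0 / (b_tau + 0.5 * q));
      }
    }

    // --- proposal adaptation (burn-in only, frozen afterwards) ---
    if (iter <= n_burn && iter % adapt_every == 0) {
      if (att[0] > 0)
        s_alpha *= clampd(std::exp(2.0 * (acc[0] / att[0] - 0.44)), 1.0 / 3, 3.0);
      for (int j = 0; j < p; ++j)
        if (att[1 + j] > 0)
          s_beta[j] *= clampd(std::exp(2.0 * (acc[1 + j] / att[1 + j] - 0.44)),
                              1.0 / 3, 3.0);
      if (att[p + 1] > 0)
        s_u *= clampd(std::exp(2.0 * (acc[p + 1] / att[p + 1] - 0.44)), 1.0 / 3, 3.0);
      if (att[p + 2] > 0)
        s_eta *= clampd(std::exp(2.0 * (acc[p + 2] / att[p + 2] - 0.44)), 1.0 / 3, 3.0);
      if (temporal) {
        if (att[p + 3] > 0)
          s_g *= clampd(std::exp(2.0 * (acc[p + 3] / att[p + 3] - 0.44)), 1.0 / 3, 3.0);
        if (att[p + 4] > 0)
          s_p *= clampd(std::exp(2.0 * (acc[p + 4] / att[p + 4] - 0.44)), 1.0 / 3, 3.0);
        if (att[p + 5] > 0)
          s_sw *= clampd(std::exp(2.0 * (acc[p + 5] / att[p + 5] - 0.44)), 1.0 / 3, 3.0);
      }
      std::fill(acc.begin(), acc.end(), 0.0);
      std::fill(att.begin(), att.end(), 0.0);
    }

    // --- store ---
    if (iter > n_burn && (iter - n_burn) % thin == 0) {
      int c = 0;
      draws(keep_row, c++) = alpha;
      for (int j = 0; j < p; ++j) draws(keep_row, c++) = beta[j];
      draws(keep_row, c++) = tau_u;
      draws(keep_row, c++) = tau_eta;
      if (temporal) {
        draws(keep_row, c++) = tau_g;
        draws(keep_row, c++) = tau_p;
      }
      for (int i = 0; i < n; ++i) draws(keep_row, c++) = u[i];
      for (int i = 0; i < n; ++i) draws(keep_row, c++) = eta[i];
      if (temporal) {
        for (int t = 0; t < T; ++t) draws(keep_row, c++) = gam[t];
        for (int t = 0; t < T; ++t) draws(keep_row, c++) = phi[t];
      }
      ++keep_row;
    }
  }

  NumericVector acc_rate(nblk);
  for (int k = 0; k < nblk; ++k)
    acc_rate[k] = att_all[k] > 0 ? acc_all[k] / att_all[k] : NA_REAL;
  return List::create(_["draws"] = draws, _["acceptance"] = acc_rate,
                      _["scales"] = List::create(
                        _["alpha"] = s_alpha, _["beta"] = s_beta,
                        _["u"] = s_u, _["eta"] = s_eta,
                        _["gamma"] = s_g, _["phi"] = s_p));
}
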