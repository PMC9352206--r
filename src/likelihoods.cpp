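#include <Rcpp.h>
using namespace Rcpp;

// Trial-loop likelihood kernels. These mirror, step for step, the exported
// R operations (q_update/pearce_hall_step/... and the grid operations);
// the R compositions are the reference path and the test suite asserts
// agreement between the two.

static const double Q_INIT = 2.5;
static const double PE_SCALE = 15.0;

// [[Rcpp::export]]
double prl_loglik_cpp(IntegerVector choice, NumericVector reward,
                      double tau, double lambda1, double lambda2,
                      double S, double phi, double eta_pr, double zeta,
                      int reversal_trial) {
  const int n = choice.size();
  const bool has_l2 = !NumericVector::is_na(lambda2);
  const bool has_S = !NumericVector::is_na(S);
  const bool has_phi = !NumericVector::is_na(phi);
  const bool has_eta = !NumericVector::is_na(eta_pr);
  const double zz = NumericVector::is_na(zeta) ? 0.0 : zeta;

  double q[3] = {Q_INIT, Q_INIT, Q_INIT};
  double salience = 1.0;
  double ll = 0.0;

  for (int i = 0; i < n; ++i) {
    const int t = i + 1;  // contiguous 1-based trials
    const int c = choice[i] - 1;
    // softmax with log-sum-exp
    double m = q[0];
    if (q[1] > m) m = q[1];
    if (q[2] > m) m = q[2];
    double e0 = std::exp((q[0] - m) / tau), e1 = std::exp((q[1] - m) / tau),
           e2 = std::exp((q[2] - m) / tau);
    double z = e0 + e1 + e2;
    // accumulate log-probabilities directly so extreme temperatures
    // (e.g. the pinned win-stay/lose-shift tau = 0.01) stay finite
    const double lp = (q[c] - m) / tau - std::log(z);
    ll += (zz > 0.0) ? std::log(zz / 3.0 + (1.0 - zz) * std::exp(lp)) : lp;

    const double lam = (has_l2 && t > reversal_trial) ? lambda2 : lambda1;
    const double pe = reward[i] - q[c];
    if (has_S) {
      salience = S * std::fabs(pe) / PE_SCALE + (1.0 - S) * salience;
      q[c] += salience * lam * pe;
    } else {
      q[c] += lam * pe;
    }
    if (has_phi) {
      for (int k = 0; k < 3; ++k)
        if (k != c) q[k] = Q_INIT - phi * (Q_INIT - q[k]);
    }
    if (has_eta && t == reversal_trial) {
      for (int k = 0; k < 3; ++k) q[k] += eta_pr * (Q_INIT - q[k]);
    }
  }
  return ll;
}

// [[Rcpp::export]]
double social_loglik_cpp(IntegerVector unfair, IntegerVector hi_bin,
                         IntegerVector si_bin, NumericMatrix prior0,
                         NumericMatrix p_unfair, double u_pi, double xi,
                         int n_eta, double eta_hi, double eta_si,
                         int reversal_trial, bool propagate_blunted) {
  const int nb = prior0.nrow();
  const int n = unfair.size();
  std::vector<double> belief(nb * nb), p0(nb * nb), post(nb * nb),
      emit(nb * nb);
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < nb; ++i) {
      p0[i + nb * j] = prior0(i, j);
      belief[i + nb * j] = prior0(i, j);
    }

  const double inv_u = 1.0 / u_pi;
  double ll = 0.0;

  for (int tr = 0; tr < n; ++tr) {
    // exact Bayes on the grid
    double z = 0.0;
    for (int j = 0; j < nb; ++j)
      for (int i = 0; i < nb; ++i) {
        const double lik = unfair[tr] ? p_unfair(i, j) : 1.0 - p_unfair(i, j);
        post[i + nb * j] = lik * belief[i + nb * j];
        z += post[i + nb * j];
      }
    if (!(z > 0.0) || !R_finite(z)) return R_NegInf;
    // blunted emission distribution
    double ze = 0.0;
    for (int k = 0; k < nb * nb; ++k) {
      post[k] /= z;
      emit[k] = std::pow(post[k], inv_u) + xi;
      ze += emit[k];
    }
    const int cell = (hi_bin[tr] - 1) + nb * (si_bin[tr] - 1);
    ll += std::log(emit[cell] / ze);

    if (propagate_blunted) {
      for (int k = 0; k < nb * nb; ++k) belief[k] = emit[k] / ze;
    } else {
      for (int k = 0; k < nb * nb; ++k) belief[k] = post[k];
    }

    if (n_eta > 0 && (tr + 1) == reversal_trial) {
      if (n_eta == 1) {
        for (int k = 0; k < nb * nb; ++k)
          belief[k] = (1.0 - eta_hi) * p0[k] + eta_hi * belief[k];
      } else {
        // mix marginals separately, rebuild joint as their product
        std::vector<double> hi0(nb, 0.0), si0(nb, 0.0), hiP(nb, 0.0),
            siP(nb, 0.0);
        for (int j = 0; j < nb; ++j)
          for (int i = 0; i < nb; ++i) {
            hi0[i] += p0[i + nb * j];
            si0[j] += p0[i + nb * j];
            hiP[i] += belief[i + nb * j];
            siP[j] += belief[i + nb * j];
          }
        double sh = 0.0, ss = 0.0;
        for (int i = 0; i < nb; ++i) {
          hiP[i] = (1.0 - eta_hi) * hi0[i] + eta_hi * hiP[i];
          siP[i] = (1.0 - eta_si) * si0[i] + eta_si * siP[i];
          sh += hiP[i];
          ss += siP[i];
        }
        for (int j = 0; j < nb; ++j)
          for (int i = 0; i < nb; ++i)
            belief[i + nb * j] = (hiP[i] / sh) * (siP[j] / ss);
      }
    }
  }
  return ll;
}

// Binomial-power prior on nb bins, computed in logs with softmax
// normalisation (matches binomial_power_prior() in R).
static void binom_power(double p, double u, int nb, double *out) {
  if (u == 0.0) {
    for (int k = 0; k < nb; ++k) out[k] = 1.0 / nb;
    return;
  }
  std::vector<double> lw(nb);
  double m = R_NegInf;
  for (int k = 0; k < nb; ++k) {
    lw[k] = u * R::dbinom(k, nb - 1, p, 1);
    if (lw[k] > m) m = lw[k];
  }
  double z = 0.0;
  for (int k = 0; k < nb; ++k) {
    out[k] = std::exp(lw[k] - m);
    z += out[k];
  }
  for (int k = 0; k < nb; ++k) out[k] /= z;
}

// Full belief-model objective kernel: builds the prior and policy map
// internally so MAP fitting avoids per-evaluation R allocations.
// [[Rcpp::export]]
double social_loglik_full_cpp(IntegerVector unfair, IntegerVector hi_bin,
                              IntegerVector si_bin, double pHI0, double uHI0,
                              double pSI0, double uSI0, double u_pi,
                              double w0, double wHI, double wSI, int n_eta,
                              double eta_hi, double eta_si,
                              int reversal_trial, double xi) {
  const int nb = 9;
  double hip[nb], sip[nb];
  binom_power(pHI0, uHI0, nb, hip);
  binom_power(pSI0, uSI0, nb, sip);
  NumericMatrix prior0(nb, nb), pmap(nb, nb);
  const double centre = (nb + 1) / 2.0;
  for (int j = 0; j < nb; ++j)
    for (int i = 0; i < nb; ++i) {
      prior0(i, j) = hip[i] * sip[j];
      const double lin = w0 + wHI * (i + 1 - centre) + wSI * (j + 1 - centre);
      pmap(i, j) = 1.0 / (1.0 + std::exp(-lin));
    }
  return social_loglik_cpp(unfair, hi_bin, si_bin, prior0, pmap, u_pi, xi,
                           n_eta, eta_hi, eta_si, reversal_trial, false);
}

// [[Rcpp::export]]
double assoc_loglik_cpp(IntegerVector unfair, NumericVector hi01,
                        NumericVector si01, double esv0, double alpha,
                        double a_wHI0, double a_wHI, double a_wSI0,
                        double a_wSI, double sigma, int n_eta,
                        double eta_hi, double eta_si, int reversal_trial) {
  const int n = unfair.size();
  double esv_hi = esv0, esv_si = esv0;
  const double lc = -0.5 * std::log(2.0 * M_PI) - std::log(sigma);
  double ll = 0.0;
  for (int tr = 0; tr < n; ++tr) {
    const double r = unfair[tr] ? 0.0 : 0.5;
    esv_hi += alpha * (r - esv_hi);
    esv_si += alpha * (r - esv_si);
    const double ph = 1.0 / (1.0 + std::exp(-(a_wHI0 + a_wHI * (esv_hi - 0.25))));
    const double ps = 1.0 / (1.0 + std::exp(-(a_wSI0 + a_wSI * (esv_si - 0.25))));
    const double dh = (hi01[tr] - ph) / sigma;
    const double ds = (si01[tr] - ps) / sigma;
    ll += 2.0 * lc - 0.5 * dh * dh - 0.5 * ds * ds;
    if (n_eta > 0 && (tr + 1) == reversal_trial) {
      esv_hi = (1.0 - eta_hi) * esv0 + eta_hi * esv_hi;
      esv_si = (1.0 - eta_si) * esv0 + eta_si * esv_si;
    }
  }
  return ll;
}
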