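#include <Rcpp.h>
using namespace Rcpp;

// log of ZINB pmf at integer k for theta = (omega, r, p).
// P(0) = omega + (1-omega)(1-p)^r ; P(k>0) = (1-omega) C(k+r-1,k) p^k (1-p)^r
static inline double zinb_logpmf_one(double k, double omega, double r,
                                     double p) {
  const double log1m_p = std::log1p(-p);
  if (k == 0.0) {
    if (omega >= 1.0) return 0.0;
    // log(omega + exp(a)) with a = log(1-omega) + r*log(1-p)
    const double a = std::log1p(-omega) + r * log1m_p;
    if (omega <= 0.0) return a;
    const double lo = std::log(omega);
    const double m = std::max(lo, a);
    return m + std::log(std::exp(lo - m) + std::exp(a - m));
  }
  if (omega >= 1.0) return R_NegInf;
  return std::log1p(-omega) + R::lgammafn(k + r) - R::lgammafn(r) -
         R::lgammafn(k + 1.0) + k * std::log(p) + r * log1m_p;
}

// [[Rcpp::export]]
NumericVector zinb_logpmf_cpp(NumericVector k, double omega, double r,
                              double p) {
  const R_xlen_t n = k.size();
  NumericVector out(n);
  for (R_xlen_t i = 0; i < n; ++i)
    out[i] = zinb_logpmf_one(k[i], omega, r, p);
  return out;
}

static inline bool in_support(double omega, double r, double p) {
  return omega >= 0.0 && omega <= 1.0 && p > 0.0 && p < 1.0 && r > 0.0;
}

// log posterior on tabulated counts (unique value k_i with multiplicity w_i):
// sum_i w_i * logpmf(k_i) + log HalfNormal(sigma_r)(r); uniform(0,1) priors
// on omega and p contribute 0 inside the support.
static inline double log_post_tab(const NumericVector& ku,
                                  const NumericVector& w, double omega,
                                  double r, double p, double sigma_r) {
  if (!in_support(omega, r, p)) return R_NegInf;
  double ll = 0.0;
  const R_xlen_t n = ku.size();
  for (R_xlen_t i = 0; i < n; ++i)
    ll += w[i] * zinb_logpmf_one(ku[i], omega, r, p);
  // half-normal log density: log(2) - log(sigma) - 0.5*log(2*pi) - r^2/(2 s^2)
  const double lprior = M_LN2 - std::log(sigma_r) - 0.5 * std::log(2.0 * M_PI) -
                        (r * r) / (2.0 * sigma_r * sigma_r);
  return ll + lprior;
}

// [[Rcpp::export]]
double zinb_log_posterior_cpp(NumericVector k_unique, NumericVector weight,
                              double omega, double r, double p,
                              double sigma_r) {
  return log_post_tab(k_unique, weight, omega, r, p, sigma_r);
}

// Metropolis-Hastings sampler for the ZINB posterior.
// Diagonal Gaussian proposal with per-coordinate SD
//   sd_j = max(proposal_frac * |theta_j|, min_proposal_sd)
// (state-scaled, hence asymmetric). When hastings = true the acceptance
// probability includes the kernel ratio q(theta | theta') / q(theta' | theta).
// Uses R's RNG so set.seed() in R makes chains reproducible.
// [[Rcpp::export]]
List mh_zinb_cpp(NumericVector k_unique, NumericVector weight, int n_iter,
                 int burn_in, int thin, double proposal_frac,
                 double min_proposal_sd, bool hastings, NumericVector init,
                 double sigma_r, double log_post_offset) {
  double th[3] = {init[0], init[1], init[2]};
  double lp = log_post_tab(k_unique, weight, th[0], th[1], th[2], sigma_r) +
              log_post_offset;
  if (!R_FINITE(lp))
    stop("initial parameter vector has zero posterior density");

  const int n_keep = (n_iter - burn_in) / thin;
  NumericMatrix samples(n_keep, 3);
  NumericVector log_post(n_keep);
  long n_accept = 0;
  int keep = 0;

  double prop[3], sd_cur[3], sd_prop[3];
  for (int it = 1; it <= n_iter; ++it) {
    for (int j = 0; j < 3; ++j) {
      sd_cur[j] = std::max(proposal_frac * std::fabs(th[j]), min_proposal_sd);
      prop[j] = R::rnorm(th[j], sd_cur[j]);
    }
    double lp_prop =
        log_post_tab(k_unique, weight, prop[0], prop[1], prop[2], sigma_r);
    double log_alpha;
    if (!R_FINITE(lp_prop)) {
      log_alpha = R_NegInf;
    } else {
      lp_prop += log_post_offset;
      log_alpha = lp_prop - lp;
      if (hastings) {
        for (int j = 0; j < 3; ++j) {
          sd_prop[j] =
              std::max(proposal_frac * std::fabs(prop[j]), min_proposal_sd);
          log_alpha += R::dnorm(th[j], prop[j], sd_prop[j], 1) -
                       R::dnorm(prop[j], th[j], sd_cur[j], 1);
        }
      }
    }
    if (log_alpha >= 0.0 || std::log(R::unif_rand()) < log_alpha) {
      th[0] = prop[0];
      th[1] = prop[1];
      th[2] = prop[2];
      lp = lp_prop;
      ++n_accept;
    }
    if (it > burn_in && (it - burn_in) % thin == 0 && keep < n_keep) {
      samples(keep, 0) = th[0];
      samples(keep, 1) = th[1];
      samples(keep, 2) = th[2];
      log_post[keep] = lp;
      ++keep;
    }
    if (it % 8192 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["samples"] = samples, _["log_post"] = log_post,
                      _["acceptance_rate"] = double(n_accept) / double(n_iter));
}

// Exact stochastic simulation (Gillespie) of the two-state telegraph model:
// OFF <-> ON promoter switching (k_on, k_off), transcription at k_tx while
// ON, first-order mRNA decay at k_deg. One terminal mRNA count per cell.
// Cells start with zero mRNA; the initial promoter state is drawn from the
// stationary switching law Bernoulli(k_on / (k_on + k_off)) so the promoter
// marginal is exact at every t.
// [[Rcpp::export]]
IntegerVector telegraph_gillespie_cpp(int n_cells, double k_on, double k_off,
                                      double k_tx, double k_deg,
                                      double t_end) {
  IntegerVector out(n_cells);
  const double p_on =
      (k_on + k_off) > 0.0 ? k_on / (k_on + k_off) : 0.0;
  for (int c = 0; c < n_cells; ++c) {
    double t = 0.0;
    int m = 0;
    bool on = R::unif_rand() < p_on;
    for (;;) {
      const double a_switch = on ? k_off : k_on;
      const double a_tx = on ? k_tx : 0.0;
      const double a_deg = k_deg * m;
      const double a_tot = a_switch + a_tx + a_deg;
      if (a_tot <= 0.0) break;
      t += R::exp_rand() / a_tot;
      if (t >= t_end) break;
      const double u = R::unif_rand() * a_tot;
      if (u < a_switch) {
        on = !on;
      } else if (u < a_switch + a_tx) {
        ++m;
      } else {
        --m;
      }
    }
    out[c] = m;
    if ((c & 1023) == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
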