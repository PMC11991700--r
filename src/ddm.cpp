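// First-passage machinery for a Wiener diffusion between absorbing bounds
// {0, a}, start z*a, within-trial diffusion sigma fixed at 1 evidence/sqrt(s),
// drift drawn per visit from Normal(v, sv^2).
//
// All densities are computed at the *lower* bound for a process with drift
// `v` and relative start `w`; the upper-bound quantities follow from the
// reflection (v, z) -> (-v, 1 - z).

#include <Rcpp.h>
#include <map>
#include <tuple>
using namespace Rcpp;

static const double LOG_EPS_TINY = -745.0; // log(~5e-324)

static void em_path(double drift, double a, double x0, double dt,
                    double max_time, double &time_out, int &bound_out);

// Standardised (a = 1, v = 0) lower-bound FPT density at u = t / a^2,
// relative start w. Series form chosen by the cheaper of the small-time
// and large-time expansions at truncation error `eps`.
static double ft_std(double u, double w, double eps) {
  if (!(u > 0.0)) return 0.0;

  // terms needed for large-time series
  double kl;
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  // terms needed for small-time series
  double ks;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }

  double f = 0.0;
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    for (int k = -K; k <= K; ++k) {
      double x = w + 2.0 * k;
      f += x * std::exp(-x * x / (2.0 * u));
    }
    f /= std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    for (int k = 1; k <= K; ++k) {
      f += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    f *= M_PI;
  }
  return std::max(f, 0.0);
}

// log of the Gaussian-drift-mixture factor
//   int N(u; v, sv^2) exp(-u a w - u^2 t / 2) du
// (reduces to exp(-v a w - v^2 t / 2) at sv = 0).
static double log_mix_factor(double t, double v, double sv, double a, double w) {
  double s2t = sv * sv * t;
  return -0.5 * std::log1p(s2t) +
    (sv * sv * a * a * w * w - 2.0 * v * a * w - v * v * t) / (2.0 * (1.0 + s2t));
}

// log f_lower(t | v, sv, a, w): density of absorption at the lower bound.
static double log_f_lower_one(double t, double v, double sv, double a, double w,
                              double eps) {
  if (!(t > 0.0)) return R_NegInf;
  double ft = ft_std(t / (a * a), w, eps);
  if (ft <= 0.0) return R_NegInf;
  return std::log(ft) - 2.0 * std::log(a) + log_mix_factor(t, v, sv, a, w);
}

// [[Rcpp::export]]
NumericVector wfpt_log_density_upper_cpp(NumericVector t, NumericVector v,
                                         NumericVector sv, double a, double z,
                                         double eps) {
  int n = t.size();
  NumericVector out(n);
  double w = 1.0 - z;
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double si = sv[sv.size() == 1 ? 0 : i];
    out[i] = log_f_lower_one(t[i], -vi, si, a, w, eps);
  }
  return out;
}

// [[Rcpp::export]]
NumericVector wfpt_log_density_lower_cpp(NumericVector t, NumericVector v,
                                         NumericVector sv, double a, double z,
                                         double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double si = sv[sv.size() == 1 ? 0 : i];
    out[i] = log_f_lower_one(t[i], vi, si, a, z, eps);
  }
  return out;
}

// P(absorb at upper bound) for fixed drift v; expm1 form is stable for
// either drift sign.
static double p_upper_fixed(double v, double a, double z) {
  if (std::fabs(v) < 1e-10) return z;
  return std::expm1(-2.0 * v * z * a) / std::expm1(-2.0 * v * a);
}

// [[Rcpp::export]]
NumericVector upper_prob_cpp(NumericVector v, NumericVector sv, double a, double z,
                             NumericVector gh_x, NumericVector gh_w) {
  int n = std::max(v.size(), sv.size());
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double si = sv[sv.size() == 1 ? 0 : i];
    if (si <= 0.0) {
      out[i] = p_upper_fixed(vi, a, z);
    } else {
      // E_u[P_upper(u)], u ~ N(vi, si^2), Gauss-Hermite: u = vi + sqrt(2) si x
      double acc = 0.0;
      for (int q = 0; q < gh_x.size(); ++q) {
        acc += gh_w[q] * p_upper_fixed(vi + M_SQRT2 * si * gh_x[q], a, z);
      }
      out[i] = acc / std::sqrt(M_PI);
    }
  }
  return out;
}

// P(T > t, upper) for fixed drift, via the exponentially convergent
// large-time series integrated term by term:
//   S(t) = (pi/a^2) exp(v a (1-z)) sum_k k sin(k pi (1-z)) exp(-lam_k t)/lam_k,
//   lam_k = (v^2 + k^2 pi^2 / a^2) / 2.
static double surv_upper_fixed(double t, double v, double a, double z,
                               double eps) {
  double w = 1.0 - z;
  double pref = (M_PI / (a * a)) * std::exp(v * a * w);
  double acc = 0.0;
  const int KMAX = 100000;
  for (int k = 1; k <= KMAX; ++k) {
    double lam = (v * v + k * k * M_PI * M_PI / (a * a)) / 2.0;
    double term = k * std::sin(k * M_PI * w) * std::exp(-lam * t) / lam;
    acc += term;
    if (k > 3 && std::fabs(term) < eps * (std::fabs(acc) + 1e-300)) break;
  }
  double s = pref * acc;
  double pu = p_upper_fixed(v, a, z);
  if (s < 0.0) s = 0.0;
  if (s > pu) s = pu;
  return s;
}

// [[Rcpp::export]]
NumericVector upper_log_survival_cpp(NumericVector t, NumericVector v,
                                     NumericVector sv, double a, double z,
                                     NumericVector gh_x, NumericVector gh_w,
                                     double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double si = sv[sv.size() == 1 ? 0 : i];
    double s;
    if (si <= 0.0) {
      s = surv_upper_fixed(t[i], vi, a, z, eps);
    } else {
      double acc = 0.0;
      for (int q = 0; q < gh_x.size(); ++q) {
        acc += gh_w[q] * surv_upper_fixed(t[i], vi + M_SQRT2 * si * gh_x[q], a, z, eps);
      }
      s = acc / std::sqrt(M_PI);
    }
    out[i] = s > 0.0 ? std::log(s) : LOG_EPS_TINY;
  }
  return out;
}

// Pointwise visit log-likelihood. Uncensored visits contribute the
// upper-bound passage density (defective: exits are upper passages).
// Censored visits contribute survival mass beyond the censoring time:
// with `censor_total = true` the total mass 1 - F_upper(t) (exits not yet
// taken plus lower-bound non-exits: the fully generative convention), with
// `false` only the upper-bound mass P(T > t, upper). `conditional = true`
// additionally normalises every term by the upper absorption probability
// (all observed visits conditioned on ending in an exit).
// [[Rcpp::export]]
NumericVector visit_pointwise_loglik_cpp(NumericVector t, LogicalVector censored,
                                         NumericVector v, NumericVector sv,
                                         double a, double z, bool conditional,
                                         bool censor_total,
                                         NumericVector gh_x, NumericVector gh_w,
                                         double eps) {
  int n = t.size();
  NumericVector out(n);
  double w = 1.0 - z;
  bool need_pu = conditional;
  for (int i = 0; i < n && !need_pu; ++i) if (censored[i]) need_pu = censor_total;
  NumericVector pu;
  if (need_pu) pu = upper_prob_cpp(v, sv, a, z, gh_x, gh_w);
  // censored terms repeat across visits sharing (t, v, sv): memoise them
  std::map<std::tuple<double, double, double>, double> cens_memo;
  for (int i = 0; i < n; ++i) {
    double vi = v[v.size() == 1 ? 0 : i];
    double si = sv[sv.size() == 1 ? 0 : i];
    double ll;
    if (censored[i]) {
      double s;
      auto key = std::make_tuple(t[i], vi, si);
      auto hit = cens_memo.find(key);
      if (hit != cens_memo.end()) {
        s = hit->second;
      } else {
        if (si <= 0.0) {
          s = surv_upper_fixed(t[i], vi, a, z, eps);
        } else {
          double acc = 0.0;
          for (int q = 0; q < gh_x.size(); ++q) {
            acc += gh_w[q] * surv_upper_fixed(t[i], vi + M_SQRT2 * si * gh_x[q], a, z, eps);
          }
          s = acc / std::sqrt(M_PI);
        }
        cens_memo[key] = s;
      }
      if (censor_total) {
        double p = pu[pu.size() == 1 ? 0 : i];
        s = 1.0 - p + s; // 1 - F_upper(t)
      }
      ll = s > 0.0 ? std::log(s) : LOG_EPS_TINY;
    } else {
      ll = log_f_lower_one(t[i], -vi, si, a, w, eps);
      if (ll < LOG_EPS_TINY) ll = LOG_EPS_TINY;
    }
    if (conditional) {
      double p = pu[pu.size() == 1 ? 0 : i];
      ll -= std::log(std::max(p, 1e-300));
    }
    out[i] = ll;
  }
  return out;
}

// Visit outcomes under the generative convention: per-visit drift draw,
// Euler path; an upper passage within `horizon` is an uncensored duration,
// anything else (lower absorption = never leaves, or slower than the
// horizon) is censored at the horizon.
// [[Rcpp::export]]
List sim_visits_censored_cpp(NumericVector v, NumericVector sv, double a,
                             double z, double dt, double horizon) {
  int n = v.size();
  NumericVector time(n), drift(n);
  LogicalVector cens(n);
  double x0 = z * a;
  for (int i = 0; i < n; ++i) {
    double si = sv[sv.size() == 1 ? 0 : i];
    double d = v[i] + si * norm_rand();
    double tt; int bb;
    em_path(d, a, x0, dt, horizon, tt, bb);
    drift[i] = d;
    if (bb == 1) { time[i] = tt; cens[i] = false; }
    else { time[i] = horizon; cens[i] = true; }
  }
  return List::create(_["time"] = time, _["censored"] = cens, _["drift"] = drift);
}

// One Euler-Maruyama path with Brownian-bridge crossing detection inside
// each step (removes the O(sqrt(dt)) boundary-miss bias). Returns
// (time, boundary) with boundary +1 upper, -1 lower, 0 not absorbed.
static void em_path(double drift, double a, double x0, double dt,
                    double max_time, double &time_out, int &bound_out) {
  double x = x0;
  double t = 0.0;
  double sdt = std::sqrt(dt);
  while (t < max_time) {
    double xn = x + drift * dt + sdt * norm_rand();
    t += dt;
    // crossings happen inside the step; report the midpoint (continuity
    // correction for the dt-grid recording)
    double tmid = t - dt / 2.0;
    if (xn >= a) { time_out = tmid; bound_out = 1; return; }
    if (xn <= 0.0) { time_out = tmid; bound_out = -1; return; }
    // bridge crossing probabilities within the completed step
    double p_up = std::exp(-2.0 * (a - x) * (a - xn) / dt);
    double p_lo = std::exp(-2.0 * x * xn / dt);
    double u = unif_rand();
    if (u < p_up) { time_out = tmid; bound_out = 1; return; }
    if (u < p_up + p_lo) { time_out = tmid; bound_out = -1; return; }
    x = xn;
  }
  time_out = max_time;
  bound_out = 0;
}

// [[Rcpp::export]]
List sim_fpt_cpp(int n, double v, double sv, double a, double z, double dt,
                 double max_time) {
  NumericVector time(n), drift(n);
  IntegerVector bound(n);
  double x0 = z * a;
  for (int i = 0; i < n; ++i) {
    double d = v + sv * norm_rand();
    double ti; int bi;
    em_path(d, a, x0, dt, max_time, ti, bi);
    time[i] = ti; bound[i] = bi; drift[i] = d;
  }
  return List::create(_["time"] = time, _["boundary"] = bound, _["drift"] = drift);
}

// Per-visit upper-boundary passage times: drift drawn per visit; lower
// absorptions (latent non-exits) are resampled, counted in n_resampled.
// [[Rcpp::export]]
List sim_visits_cpp(NumericVector v, NumericVector sv, double a, double z,
                    double dt, double max_time, int max_tries) {
  int n = v.size();
  NumericVector time(n), drift(n);
  int n_resampled = 0, n_failed = 0;
  double x0 = z * a;
  for (int i = 0; i < n; ++i) {
    double si = sv[sv.size() == 1 ? 0 : i];
    double ti = NA_REAL, di = NA_REAL;
    bool ok = false;
    for (int tr = 0; tr < max_tries; ++tr) {
      double d = v[i] + si * norm_rand();
      double tt; int bb;
      em_path(d, a, x0, dt, max_time, tt, bb);
      if (bb == 1) { ti = tt; di = d; ok = true; break; }
      ++n_resampled;
    }
    if (!ok) ++n_failed;
    time[i] = ti; drift[i] = di;
  }
  return List::create(_["time"] = time, _["drift"] = drift,
                      _["n_resampled"] = n_resampled, _["n_failed"] = n_failed);
}
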