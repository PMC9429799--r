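// First-passage-time machinery for the Wiener diffusion model with two
// absorbing boundaries (diffusion constant fixed at 1).
//
// Conventions: boundary separation a > 0, relative starting point w in (0,1)
// (absolute start z = w * a), drift v (evidence / second), time in seconds.
// The lower boundary sits at 0, the upper at a.  Defective distributions:
// F_lower(t) + F_upper(t) -> 1 as t -> Inf.
//
// Two complementary series are used for the defective CDF:
//  * small-time: image expansion; each image term integrates in closed form
//    to a pair of Mills-ratio terms evaluated via log-Phi (stable for large
//    arguments);
//  * large-time: termwise integration of the sine series, whose tail decays
//    like exp(-k^2 pi^2 t / (2 a^2)).
// The switch point is t/a^2 = 0.35, where both series need only a handful of
// terms for absolute error ~1e-9.  Densities follow the standard
// small/large-time selection rule at target error 1e-7.

#include <Rcpp.h>
using namespace Rcpp;

static const double T_STAR_SWITCH = 0.08;
static const double SERIES_EPS = 1e-9;

// P(absorb at upper boundary), closed form; stable for extreme v*a.
// [[Rcpp::export(name = "prob_upper_cpp")]]
double prob_upper_cpp(double v, double a, double w) {
  double z = w * a;
  if (std::fabs(v) < 1e-10) return w;
  double ea = -2.0 * v * a, ez = -2.0 * v * z;
  // v strongly negative: both expm1 overflow; ratio tends to e^{2 v (a - z)}
  if (ea > 500.0) return std::exp(ez - ea);
  return std::expm1(ez) / std::expm1(ea);
}

// Defective CDF at the lower boundary, decision time t (no variability).
// [[Rcpp::export(name = "wfpt_cdf_lower_cpp")]]
double wfpt_cdf_lower_cpp(double t, double v, double a, double w) {
  if (t <= 0.0) return 0.0;
  double p_lower = 1.0 - prob_upper_cpp(v, a, w);
  double t_star = t / (a * a);
  if (t_star > T_STAR_SWITCH) {
    // large-time: F = P_lower - (pi/a^2) e^{-v a w} sum_k k sin(k pi w)
    //                  e^{-lambda_k t} / lambda_k
    // exp(-lambda_k t) = E q^{k^2} and sin(k pi w) evaluated by
    // multiply-only recurrences, so each term costs a few flops.
    double pref = M_PI / (a * a) * std::exp(-v * a * w);
    double E = std::exp(-0.5 * v * v * t);
    double q = std::exp(-0.5 * M_PI * M_PI / (a * a) * t);
    double q2 = q * q;
    double lam0 = 0.5 * v * v, lamk = 0.5 * M_PI * M_PI / (a * a);
    double s1 = std::sin(M_PI * w), c1 = 2.0 * std::cos(M_PI * w);
    double sin_prev = 0.0, sin_cur = s1;       // sin(0), sin(pi w)
    double qk2 = q;                            // q^{k^2} at k = 1
    double rk = q * q2;                        // q^{2k+1} at k = 1
    double sum = 0.0;
    for (int k = 1; k <= 512; ++k) {
      double lam = lam0 + lamk * k * k;
      sum += k * sin_cur * E * qk2 / lam;
      // advance recurrences to k + 1
      double sin_next = c1 * sin_cur - sin_prev;
      sin_prev = sin_cur; sin_cur = sin_next;
      qk2 *= rk; rk *= q2;
      if (pref * (k + 1) * E * qk2 / lam < SERIES_EPS && k >= 2) break;
    }
    double val = p_lower - pref * sum;
    if (val < 0.0) val = 0.0;
    if (val > p_lower) val = p_lower;
    return val;
  }
  // small-time image expansion: terms k = 0, -1, 1, -2, 2, ...
  double av = std::fabs(v);
  double sqt = std::sqrt(t);
  double sum = 0.0;
  int small_streak = 0;
  for (int j = 0; j <= 100; ++j) {
    int k = (j % 2 == 0) ? -(j / 2) : (j + 1) / 2; // 0, 1, -1, 2, -2...
    // order is immaterial; track consecutive negligible terms
    double q = w + 2.0 * k;
    double sgn = (q >= 0.0) ? 1.0 : -1.0;
    double b = a * std::fabs(q);
    double lp1 = R::pnorm(( av * t - b) / sqt, 0.0, 1.0, 1, 1);
    double lp2 = R::pnorm((-av * t - b) / sqt, 0.0, 1.0, 1, 1);
    double term = sgn * (std::exp(-v * a * w - b * av + lp1) +
                         std::exp(-v * a * w + b * av + lp2));
    sum += term;
    if (std::fabs(term) < SERIES_EPS * 1e-2) {
      if (++small_streak >= 2 && j >= 2) break;
    } else small_streak = 0;
  }
  if (sum < 0.0) sum = 0.0;
  if (sum > p_lower) sum = p_lower;
  return sum;
}

// [[Rcpp::export(name = "wfpt_cdf_upper_cpp")]]
double wfpt_cdf_upper_cpp(double t, double v, double a, double w) {
  return wfpt_cdf_lower_cpp(t, -v, a, 1.0 - w);
}

// Dimensionless first-passage density at the lower boundary for a unit
// diffusion on (0,1), start w, zero drift; standard small/large-time series
// with the term-count selection rule at target error eps.
static double f0_density(double t_star, double w, double eps) {
  double ks = 2.0 + std::sqrt(std::max(0.0,
      -2.0 * t_star * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * t_star))));
  ks = std::max(ks, std::sqrt(t_star) + 1.0);
  double kl = std::sqrt(std::max(0.0,
      -2.0 * std::log(M_PI * t_star * eps) / (M_PI * M_PI * t_star)));
  kl = std::max(kl, 1.0 / (M_PI * std::sqrt(t_star)));
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    double sum = 0.0;
    for (int k = -((K - 1) / 2); k <= (K - 1) / 2 + ((K - 1) % 2); ++k) {
      double q = w + 2.0 * k;
      sum += q * std::exp(-q * q / (2.0 * t_star));
    }
    return sum / std::sqrt(2.0 * M_PI * t_star * t_star * t_star);
  }
  int K = (int)std::ceil(kl);
  double sum = 0.0;
  for (int k = 1; k <= K; ++k)
    sum += k * std::exp(-k * k * M_PI * M_PI * t_star / 2.0) *
           std::sin(k * M_PI * w);
  return M_PI * sum;
}

// Defective first-passage density, no variability.  boundary: 0 lower, 1 upper.
// [[Rcpp::export(name = "wfpt_pdf_cpp")]]
double wfpt_pdf_cpp(double t, double v, double a, double w, int upper,
                    double eps = 1e-7) {
  if (t <= 0.0) return 0.0;
  double vv = upper ? -v : v;
  double ww = upper ? 1.0 - w : w;
  double t_star = t / (a * a);
  double val = std::exp(-vv * a * ww - vv * vv * t / 2.0) *
               f0_density(t_star, ww, eps) / (a * a);
  return val > 0.0 ? val : 0.0;
}

// Joint signed CDF G(s) = P(Ttilde <= s) of the signed response variable
// (+RT at the upper/face boundary, -RT at the lower/noise boundary),
// marginalized over drift (nodes vn/vw), starting point (wn/ww) and
// non-decision time (tn/tw: absolute non-decision times with weights).
// All node weights must each sum to 1.
// [[Rcpp::export(name = "joint_cdf_grid_cpp")]]
NumericVector joint_cdf_grid_cpp(NumericVector s, double a,
                                 NumericVector vn, NumericVector vw,
                                 NumericVector wn, NumericVector ww,
                                 NumericVector tn, NumericVector tw) {
  int ns = s.size();
  NumericVector out(ns);
  double p_lower_bar = 0.0;
  for (int i = 0; i < vn.size(); ++i)
    for (int j = 0; j < wn.size(); ++j)
      p_lower_bar += vw[i] * ww[j] * (1.0 - prob_upper_cpp(vn[i], a, wn[j]));
  for (int m = 0; m < ns; ++m) {
    double acc = 0.0;
    double at = std::fabs(s[m]);
    bool up = s[m] >= 0.0;
    for (int i = 0; i < vn.size(); ++i) {
      for (int j = 0; j < wn.size(); ++j) {
        double wij = vw[i] * ww[j];
        for (int k = 0; k < tn.size(); ++k) {
          double tau = at - tn[k];
          if (tau <= 0.0) continue;
          double F = up ? wfpt_cdf_upper_cpp(tau, vn[i], a, wn[j])
                        : wfpt_cdf_lower_cpp(tau, vn[i], a, wn[j]);
          acc += wij * tw[k] * (up ? F : -F);
        }
      }
    }
    out[m] = p_lower_bar + acc;
    if (out[m] < 0.0) out[m] = 0.0;
    if (out[m] > 1.0) out[m] = 1.0;
  }
  return out;
}

// Marginal signed joint density g(s) at each signed response time.
// [[Rcpp::export(name = "joint_pdf_grid_cpp")]]
NumericVector joint_pdf_grid_cpp(NumericVector s, double a,
                                 NumericVector vn, NumericVector vw,
                                 NumericVector wn, NumericVector ww,
                                 NumericVector tn, NumericVector tw,
                                 double eps = 1e-7) {
  int ns = s.size();
  NumericVector out(ns);
  for (int m = 0; m < ns; ++m) {
    double acc = 0.0;
    double at = std::fabs(s[m]);
    int up = s[m] >= 0.0 ? 1 : 0;
    for (int k = 0; k < tn.size(); ++k) {
      double tau = at - tn[k];
      if (tau <= 0.0) continue;
      for (int i = 0; i < vn.size(); ++i)
        for (int j = 0; j < wn.size(); ++j)
          acc += vw[i] * ww[j] * tw[k] *
                 wfpt_pdf_cpp(tau, vn[i], a, wn[j], up, eps);
    }
    out[m] = acc;
  }
  return out;
}

// Euler--Maruyama simulation of decision trials.  Per trial the drift is
// Normal(v, sv), the start Uniform(zr +/- sz/2) and the non-decision time
// Uniform(t0 +/- st0/2).  Returns a matrix with columns (upper, rt_seconds).
// Uses R's RNG, so set.seed() on the R side controls reproducibility.
// [[Rcpp::export(name = "simulate_wiener_cpp")]]
NumericMatrix simulate_wiener_cpp(int n, double a, double zr, double v,
                                  double t0, double sv, double sz, double st0,
                                  double dt = 5e-4, double t_max = 30.0) {
  NumericMatrix out(n, 2);
  double sdt = std::sqrt(dt);
  int max_steps = (int)(t_max / dt);
  for (int i = 0; i < n; ++i) {
    double vi = sv > 0.0 ? R::rnorm(v, sv) : v;
    double wi = sz > 0.0 ? zr + sz * (R::unif_rand() - 0.5) : zr;
    double ndt = st0 > 0.0 ? t0 + st0 * (R::unif_rand() - 0.5) : t0;
    double x = wi * a;
    int step = 0;
    int hit = -1; // 0 lower, 1 upper
    double mu_dt = vi * dt;
    while (hit < 0 && step < max_steps) {
      double xn = x + mu_dt + sdt * R::norm_rand();
      ++step;
      if (xn >= a) { hit = 1; }
      else if (xn <= 0.0) { hit = 0; }
      else {
        // Brownian-bridge correction: probability the within-step path
        // crossed a boundary even though both endpoints are interior
        double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
        if (R::unif_rand() < pu) hit = 1;
        else if (R::unif_rand() < std::exp(-2.0 * x * xn / dt)) hit = 0;
      }
      x = xn;
    }
    int upper = hit >= 0 ? hit : (x >= a * wi ? 1 : 0);
    out(i, 0) = upper;
    out(i, 1) = step * dt + ndt;
  }
  return out;
}
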