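// Two-boundary drift-diffusion primitives.
//
// Convention: diffusion coefficient fixed at 1, time in seconds, boundaries at
// 0 (lower) and b (upper), start point z in (0, b) expressed internally as the
// relative position w = z / b.  The first-passage density through the lower
// boundary uses the dual series representation: a small-time expansion in
// image terms and a large-time eigenfunction expansion, with the truncation
// depth chosen adaptively from the requested absolute error so the cheaper of
// the two series is always used.

#include <Rcpp.h>
using namespace Rcpp;

static const double LOG_ZERO = -std::numeric_limits<double>::infinity();

// Log density of first passage through the LOWER boundary at decision time
// u > 0 (u excludes non-decision time), boundary separation b, drift v,
// relative start w, absolute truncation error err on the normalised density.
// Returns -Inf outside the support.
static double wfpt_log_lower(double u, double b, double v, double w, double err) {
  if (!(u > 0.0) || !(b > 0.0) || !(w > 0.0) || !(w < 1.0))
    return -std::numeric_limits<double>::infinity();
  double tt = u / (b * b);  // time in boundary-normalised units

  // choose the cheaper expansion; the bound computations (standard crossover
  // rule) are skipped where one series is clearly cheaper
  bool small_time;
  double ks = 2.0, kl = 1.0;
  if (tt < 0.08) {
    small_time = true;
  } else if (tt > 1.5) {
    small_time = false;
  } else {
    if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
      ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
      ks = std::max(ks, std::sqrt(tt) + 1.0);
    }
    if (M_PI * tt * err < 1.0) {
      kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
      kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    } else {
      kl = 1.0 / (M_PI * std::sqrt(tt));
    }
    small_time = ks < kl;
  }

  double p = 0.0;
  if (small_time) {
    if (tt < 0.08) {  // bound not yet computed on the fast path
      if (2.0 * std::sqrt(2.0 * M_PI * tt) * err < 1.0) {
        ks = 2.0 + std::sqrt(-2.0 * tt * std::log(2.0 * err * std::sqrt(2.0 * M_PI * tt)));
        ks = std::max(ks, std::sqrt(tt) + 1.0);
      }
    }
    int K = (int)std::ceil(ks);
    int lo = -((K - 1) / 2);
    int hi = (K - 1) / 2 + (K - 1) % 2;
    double inv2t = 1.0 / (2.0 * tt);
    for (int k = lo; k <= hi; ++k) {
      double wk = w + 2.0 * k;
      p += wk * std::exp(-wk * wk * inv2t);
    }
    p /= std::sqrt(2.0 * M_PI * tt * tt * tt);
  } else {
    if (tt > 1.5 && M_PI * tt * err < 1.0) {
      kl = std::sqrt(-2.0 * std::log(M_PI * tt * err) / (M_PI * M_PI * tt));
      kl = std::max(kl, 1.0 / (M_PI * std::sqrt(tt)));
    }
    int K = (int)std::ceil(kl);
    double c = M_PI * M_PI * tt / 2.0;
    if (w == 0.5) {  // sin(k pi / 2) vanishes for even k, alternates for odd
      for (int k = 1; k <= K; k += 2)
        p += ((k & 2) ? -k : k) * std::exp(-k * k * c);
    } else {
      for (int k = 1; k <= K; ++k)
        p += k * std::exp(-k * k * c) * std::sin(k * M_PI * w);
    }
    p *= M_PI;
  }
  if (!(p > 0.0)) return -std::numeric_limits<double>::infinity();

  // un-normalise: drift/start factor and the 1/b^2 time scaling
  return std::log(p) - v * b * w - v * v * u / 2.0 - 2.0 * std::log(b);
}

static inline double wfpt_lower(double u, double b, double v, double w, double err) {
  double lf = wfpt_log_lower(u, b, v, w, err);
  return R_finite(lf) ? std::exp(lf) : 0.0;
}

//' First-passage-time density of the two-boundary diffusion (vectorised).
//'
//' @param t decision times in seconds, measured from diffusion onset
//'   (non-decision time already subtracted).
//' @param upper integer, 1 for the upper boundary, 0 for the lower.
//' @param b,v,w parameter vectors recycled against t: boundary separation,
//'   drift, relative start point.
//' @param err absolute truncation error of the series.
//' @noRd
// [[Rcpp::export(name = ".wfpt_density_cpp")]]
NumericVector wfpt_density_cpp(NumericVector t, IntegerVector upper,
                               NumericVector b, NumericVector v,
                               NumericVector w, double err) {
  int n = t.size();
  NumericVector out(n);
  int nb = b.size(), nv = v.size(), nw = w.size(), nu = upper.size();
  for (int i = 0; i < n; ++i) {
    double bi = b[i % nb], vi = v[i % nv], wi = w[i % nw];
    if (upper[i % nu] == 1) {
      // reflection: upper-boundary density equals lower density under (-v, 1-w)
      out[i] = wfpt_lower(t[i], bi, -vi, 1.0 - wi, err);
    } else {
      out[i] = wfpt_lower(t[i], bi, vi, wi, err);
    }
  }
  return out;
}

//' Per-group sums of trial log-likelihoods.
//'
//' Each trial i has rt[i] (seconds), response boundary upper[i] (0/1), signed
//' drift v[i] (sign already set by the stimulus side), boundary b[i],
//' non-decision time t0[i], relative start w, and a 1-based group id gid[i]
//' (e.g. subject, or subject x condition cell).  Returns the summed log
//' density per group; a trial with rt <= t0 or invalid parameters contributes
//' -Inf.
//' @noRd
// [[Rcpp::export(name = ".wfpt_loglik_grouped_cpp")]]
NumericVector wfpt_loglik_grouped_cpp(NumericVector rt, IntegerVector upper,
                                      NumericVector b, NumericVector v,
                                      NumericVector t0, double w, double err,
                                      IntegerVector gid, int ngroups) {
  NumericVector out(ngroups);
  int n = rt.size();
  for (int i = 0; i < n; ++i) {
    int g = gid[i] - 1;
    if (!R_finite(out[g])) continue;  // group already impossible
    double u = rt[i] - t0[i];
    if (!(u > 0.0) || !(t0[i] >= 0.0) || !(b[i] > 0.0)) {
      out[g] = LOG_ZERO;
    } else if (upper[i] == 1) {
      out[g] += wfpt_log_lower(u, b[i], -v[i], 1.0 - w, err);
    } else {
      out[g] += wfpt_log_lower(u, b[i], v[i], w, err);
    }
  }
  return out;
}

//' Euler-Maruyama simulation of first-passage samples.
//'
//' Simulates n independent trials with per-trial parameters (recycled).  Uses
//' R's RNG so results are governed by set.seed().  When correct != 0 the
//' absorption thresholds are pulled inward by 0.5826*sqrt(dt) (the continuity
//' correction for discretely monitored barriers), removing the O(sqrt(dt))
//' first-passage bias of the plain discrete walk.  Returns a 3-column matrix:
//' decision time (s), boundary (0 lower / 1 upper), censored flag (walk hit
//' the time cap before absorption; decision time is then the cap).
//' @noRd
// [[Rcpp::export(name = ".ddm_simulate_cpp")]]
NumericMatrix ddm_simulate_cpp(int n, NumericVector b, NumericVector v,
                               NumericVector z, double dt, double cap,
                               int correct = 1) {
  NumericMatrix out(n, 3);
  int nb = b.size(), nv = v.size(), nz = z.size();
  double sdt = std::sqrt(dt);
  int max_steps = (int)std::ceil(cap / dt);
  for (int i = 0; i < n; ++i) {
    double bi = b[i % nb], vi = v[i % nv], x = z[i % nz];
    double delta = correct ? 0.5826 * sdt : 0.0;
    if (2.0 * delta >= bi || x <= delta || x >= bi - delta) delta = 0.0;
    double lo = delta, hi = bi - delta;
    double drift_dt = vi * dt;
    int step = 0;
    int hit = -1;
    while (step < max_steps) {
      x += drift_dt + sdt * norm_rand();
      ++step;
      if (x >= hi) { hit = 1; break; }
      if (x <= lo) { hit = 0; break; }
    }
    out(i, 0) = step * dt;
    out(i, 1) = (hit < 0) ? NA_REAL : (double)hit;
    out(i, 2) = (hit < 0) ? 1.0 : 0.0;
  }
  return out;
}
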