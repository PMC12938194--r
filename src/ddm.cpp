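#include <Rcpp.h>
using namespace Rcpp;

// Wiener first-passage-time density at the LOWER boundary for a diffusion
// with drift v, boundary separation a, start proportion w (measured from the
// lower boundary) and unit diffusion coefficient, evaluated at decision time
// t (already net of non-decision time).  Small-time and large-time series
// representations are selected by whichever needs fewer terms for the
// requested truncation error eps (both series are alternating-tail bounded).

static double wfpt_f_lower(double t, double v, double a, double w, double eps) {
  if (t <= 0.0 || !R_finite(t)) return 0.0;
  double u = t / (a * a);  // normalized time

  // terms needed by each representation
  double ks, kl;
  if (2.0 * std::sqrt(2.0 * M_PI * u) * eps < 1.0) {
    ks = 2.0 + std::sqrt(-2.0 * u * std::log(2.0 * eps * std::sqrt(2.0 * M_PI * u)));
    ks = std::max(ks, std::sqrt(u) + 1.0);
  } else {
    ks = 2.0;
  }
  if (M_PI * u * eps < 1.0) {
    kl = std::sqrt(-2.0 * std::log(M_PI * u * eps) / (M_PI * M_PI * u));
    kl = std::max(kl, 1.0 / (M_PI * std::sqrt(u)));
  } else {
    kl = 1.0 / (M_PI * std::sqrt(u));
  }

  double p; // density in normalized time at zero drift
  if (ks < kl) {
    int K = (int)std::ceil(ks);
    double s = 0.0;
    for (int k = -(K - 1) / 2; k <= K / 2; ++k) {
      double x = w + 2.0 * k;
      s += x * std::exp(-x * x / (2.0 * u));
    }
    p = s / std::sqrt(2.0 * M_PI * u * u * u);
  } else {
    int K = (int)std::ceil(kl);
    double s = 0.0;
    for (int k = 1; k <= K; ++k) {
      s += k * std::exp(-k * k * M_PI * M_PI * u / 2.0) * std::sin(k * M_PI * w);
    }
    p = s * M_PI;
  }
  if (p < 0.0) p = 0.0; // truncation can leave tiny negative residue

  // map back: drift term and time scaling
  double dens = p * std::exp(-v * a * w - v * v * t / 2.0) / (a * a);
  return dens > 0.0 ? dens : 0.0;
}

// density at a named boundary; upper boundary via (v, w) -> (-v, 1 - w)
static double wfpt_dens(double t, double v, double a, double w, bool upper,
                        double eps) {
  if (upper) return wfpt_f_lower(t, -v, a, 1.0 - w, eps);
  return wfpt_f_lower(t, v, a, w, eps);
}

static const double LOGDENS_FLOOR = -700.0;

static double wfpt_logdens(double rt, int acc, double v, double a, double t0,
                           double z, double eps) {
  double t = rt - t0;
  if (t <= 0.0) return LOGDENS_FLOOR;
  double d = wfpt_dens(t, v, a, z, acc == 1, eps);
  if (d <= 0.0 || !R_finite(d)) return LOGDENS_FLOOR;
  double ld = std::log(d);
  return ld < LOGDENS_FLOOR ? LOGDENS_FLOOR : ld;
}

// [[Rcpp::export]]
NumericVector wfpt_density_cpp(NumericVector t, double v, double a, double t0,
                               double z, bool upper, double eps) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double td = t[i] - t0;
    out[i] = (td > 0.0) ? wfpt_dens(td, v, a, z, upper, eps) : 0.0;
  }
  return out;
}

// Per-trial accuracy-coded log densities (correct -> upper boundary).
// [[Rcpp::export]]
NumericVector wfpt_loglik_trials_cpp(NumericVector rt, IntegerVector acc,
                                     NumericVector v, NumericVector a,
                                     NumericVector t0, NumericVector z,
                                     double eps) {
  int n = rt.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    out[i] = wfpt_logdens(rt[i], acc[i], v[i], a[i], t0[i], z[i], eps);
  }
  return out;
}

// Group-summed log likelihood: trial i belongs to group grp[i] (1-based),
// with per-group parameters.  Returns per-group sums; the workhorse of the
// component-wise Metropolis-Hastings sampler.
// [[Rcpp::export]]
NumericVector wfpt_loglik_groups_cpp(NumericVector rt, IntegerVector acc,
                                     IntegerVector grp, int n_groups,
                                     NumericVector v, NumericVector a,
                                     NumericVector t0, NumericVector z,
                                     double eps) {
  int n = rt.size();
  NumericVector out(n_groups);
  for (int i = 0; i < n; ++i) {
    int g = grp[i] - 1;
    out[g] += wfpt_logdens(rt[i], acc[i], v[g], a[g], t0[g], z[g], eps);
  }
  return out;
}

// Pointwise log-likelihood matrix (draws x trials) for LOO/AIC machinery.
// Parameter matrices are draws x n_groups; trial i uses column grp[i].
// [[Rcpp::export]]
NumericMatrix pointwise_loglik_cpp(NumericVector rt, IntegerVector acc,
                                   IntegerVector grp, NumericMatrix v,
                                   NumericMatrix a, NumericMatrix t0,
                                   NumericMatrix z, double eps) {
  int n = rt.size(), S = v.nrow();
  NumericMatrix out(S, n);
  for (int s = 0; s < S; ++s) {
    for (int i = 0; i < n; ++i) {
      int g = grp[i] - 1;
      out(s, i) = wfpt_logdens(rt[i], acc[i], v(s, g), a(s, g), t0(s, g),
                               z(s, g), eps);
    }
  }
  return out;
}

// Forward Euler-Maruyama simulation of the diffusion: unit diffusion
// coefficient, step dt, hard cap on decision time; capped trials are
// resampled.  A Brownian-bridge correction accounts for boundary crossings
// between grid points, removing the leading overshoot bias of the plain
// Euler scheme.  Returns decision time and boundary hit (1 = upper).
// Uses R's RNG so set.seed() on the R side governs reproducibility.
// [[Rcpp::export]]
List simulate_fpt_cpp(int n, double v, double a, double z, double dt,
                      double cap) {
  NumericVector t_dec(n);
  IntegerVector upper(n);
  double sdt = std::sqrt(dt);
  int max_steps = (int)std::ceil(cap / dt);
  for (int i = 0; i < n; ++i) {
    for (;;) { // resample until the trial terminates within the cap
      double x = z * a;
      int step = 0;
      int hit = -1;
      while (step < max_steps) {
        double xn = x + v * dt + sdt * norm_rand();
        ++step;
        if (xn >= a) { hit = 1; }
        else if (xn <= 0.0) { hit = 0; }
        else {
          // bridge probability of an unobserved crossing within the step
          double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
          double pd = std::exp(-2.0 * x * xn / dt);
          double u = unif_rand();
          if (u < pu) hit = 1;
          else if (u < pu + pd) hit = 0;
        }
        if (hit >= 0) break;
        x = xn;
      }
      if (hit >= 0) {
        t_dec[i] = step * dt;
        upper[i] = hit;
        break;
      }
    }
  }
  return List::create(_["t_dec"] = t_dec, _["upper"] = upper);
}
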