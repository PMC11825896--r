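#include <Rcpp.h>
#include <random>
using namespace Rcpp;

// First-passage-time machinery for a unit-diffusion Wiener process between
// absorbing boundaries at 0 and a, started at z = w0 * a with drift v.
// Densities are "defective": each boundary's density integrates to that
// boundary's hitting probability.
//
// Both series below are for the drift-free, unit-boundary process in scaled
// time tau = t / a^2 with scaled start w; drift and boundary scale re-enter
// through an exponential tilt and a 1/a^2 Jacobian. Everything is evaluated
// in the log domain so that extreme parameter values (visited by the
// optimizer) degrade to -Inf-like floors instead of overflowing.

static const double TERM_TOL = 1e-9;
static const double LOG_FLOOR = -1e10;  // stand-in for log(0)

// log of the scaled lower-boundary density, small-time (image) expansion:
// the k = 0 image dominates; the others enter through log1p of their
// ratios, which decay doubly exponentially. Terms are added outward until
// their contribution falls below TERM_TOL.
static double log_f1_small(double tau, double w) {
  const double lead = -0.5 * std::log(2.0 * M_PI) - 1.5 * std::log(tau) +
    std::log(w) - w * w / (2.0 * tau);
  double rest = 0.0;
  for (int k = 1; k < 1000; ++k) {
    double up = w + 2.0 * k, dn = w - 2.0 * k;
    double ru = (up / w) * std::exp(-(up * up - w * w) / (2.0 * tau));
    double rd = (dn / w) * std::exp(-(dn * dn - w * w) / (2.0 * tau));
    rest += ru + rd;
    if (k >= 2 && std::fabs(ru) < TERM_TOL && std::fabs(rd) < TERM_TOL)
      break;
  }
  if (rest <= -1.0) return LOG_FLOOR;  // numerically non-positive density
  return lead + std::log1p(rest);
}

// log of the same quantity, large-time (eigenfunction) expansion; the k = 1
// eigenmode dominates for tau beyond ~0.15
static double log_f1_large(double tau, double w) {
  const double s1 = std::sin(M_PI * w);
  const double lead = std::log(M_PI) + std::log(s1) -
    0.5 * M_PI * M_PI * tau;
  double rest = 0.0;
  for (int k = 2; k < 10000; ++k) {
    double r = (k * std::sin(k * M_PI * w) / s1) *
      std::exp(-0.5 * (k * k - 1.0) * M_PI * M_PI * tau);
    rest += r;
    if (k >= 3 && (k / s1) *
        std::exp(-0.5 * (k * k - 1.0) * M_PI * M_PI * tau) < TERM_TOL)
      break;
  }
  if (rest <= -1.0) return LOG_FLOOR;
  return lead + std::log1p(rest);
}

static double log_f1(double tau, double w, int method) {
  if (method == 1) return log_f1_small(tau, w);
  if (method == 2) return log_f1_large(tau, w);
  return (tau < 0.15) ? log_f1_small(tau, w) : log_f1_large(tau, w);
}

// log defective FPT density; upper[i] selects the admit (upper) boundary.
// t, upper are parallel vectors (drift may be length 1).
// method: 0 = automatic series switch, 1 = small-time, 2 = large-time.
// [[Rcpp::export]]
NumericVector wfpt_logdens_cpp(NumericVector t, NumericVector drift,
                               double a, double w0, LogicalVector upper,
                               int method) {
  const int n = t.size();
  const bool scalar_drift = (drift.size() == 1);
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double ti = t[i];
    if (!(ti > 0.0)) stop("first-passage time must be > 0");
    double v = scalar_drift ? drift[0] : drift[i];
    double w = w0;
    if (upper[i]) { v = -v; w = 1.0 - w0; }  // reflect to a lower-boundary problem
    double tau = ti / (a * a);
    double lf1 = log_f1(tau, w, method);
    if (!std::isfinite(lf1) || lf1 <= LOG_FLOOR) { out[i] = LOG_FLOOR; continue; }
    double ld = -v * w * a - 0.5 * v * v * ti - 2.0 * std::log(a) + lf1;
    if (!std::isfinite(ld) || ld < LOG_FLOOR) ld = LOG_FLOOR;
    out[i] = ld;
  }
  return out;
}

// Euler simulation of the first boundary crossed and its time, with a
// Brownian-bridge crossing check inside each step so that boundary hits
// between grid points are not missed. drift has length 1 or n.
// [[Rcpp::export]]
List wfpt_sim_cpp(NumericVector drift, int n, double a, double w0,
                  double dt, int seed) {
  const bool scalar_drift = (drift.size() == 1);
  std::mt19937_64 gen(static_cast<uint64_t>(seed));
  std::normal_distribution<double> rnorm01(0.0, 1.0);
  std::uniform_real_distribution<double> runif01(0.0, 1.0);
  const double sdt = std::sqrt(dt);
  IntegerVector admit(n);
  NumericVector time(n);
  for (int i = 0; i < n; ++i) {
    const double v = scalar_drift ? drift[0] : drift[i];
    double x = w0 * a, t = 0.0;
    int hit = -1;
    while (hit < 0) {
      double xn = x + v * dt + sdt * rnorm01(gen);
      t += dt;
      if (xn >= a) { hit = 1; }
      else if (xn <= 0.0) { hit = 0; }
      else {
        // bridge probabilities of an unobserved excursion beyond a boundary
        double pu = std::exp(-2.0 * (a - x) * (a - xn) / dt);
        double pl = std::exp(-2.0 * x * xn / dt);
        double u = runif01(gen);
        if (u < pu) hit = 1; else if (u < pu + pl) hit = 0;
      }
      x = xn;
    }
    admit[i] = hit;
    time[i] = t;
  }
  return List::create(_["admit"] = admit, _["time"] = time);
}
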