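#include <Rcpp.h>
using namespace Rcpp;

// Draw a uniformly distributed unit 2-vector.
static inline void runit2(double &ux, double &uy) {
  double th = 2.0 * M_PI * unif_rand();
  ux = std::cos(th);
  uy = std::sin(th);
}

// New migration direction: normalize((1-b)*xi + b*d), xi uniform unit vector.
// An exactly cancelling draw (norm ~ 0) is re-drawn.
static inline void turn(double b, double dx, double dy,
                        double &ox, double &oy) {
  if (b >= 1.0 && dx * dx + dy * dy < 1e-24) { runit2(ox, oy); return; }
  for (;;) {
    double ux, uy;
    runit2(ux, uy);
    double vx = (1.0 - b) * ux + b * dx;
    double vy = (1.0 - b) * uy + b * dy;
    double n = std::sqrt(vx * vx + vy * vy);
    if (n > 1e-12) { ox = vx / n; oy = vy / n; return; }
  }
}

// Biased persistent random walk on a fixed mechanics step grid.
//
// Direction turns are Bernoulli(dt/tau) per mechanics step of size dt;
// between turns a cell moves in a straight line at its own speed, so the
// walk is integrated exactly between turn events (gaps drawn as geometric
// step counts, identical in law to the per-step Bernoulli scheme).
// Positions are emitted on the sampling grid (every `steps_per_sample`
// mechanics steps), all cells starting at the origin at t = 0.
//
// speeds: per-cell speed (um/min); b: shared bias in [0,1];
// (dx, dy): unit bias direction; n_samples counts the samples after t=0.
// [[Rcpp::export]]
List bprw_tracks_cpp(NumericVector speeds, double b, double dx, double dy,
                     double tau, double dt, int steps_per_sample,
                     int n_samples) {
  int n = speeds.size();
  double p = dt / tau;
  if (p > 1.0) p = 1.0;
  double lq = std::log1p(-p); // log(1-p); p==1 handled separately
  NumericMatrix X(n, n_samples + 1), Y(n, n_samples + 1);
  for (int i = 0; i < n; i++) {
    double x = 0.0, y = 0.0;
    double cx, cy;              // current direction: drawn by the turn rule
    turn(b, dx, dy, cx, cy);
    double step_len = speeds[i] * dt;
    // steps remaining until the next turn event
    long gap;
    if (p >= 1.0) gap = 1;
    else gap = 1 + (long)std::floor(std::log(unif_rand()) / lq);
    X(i, 0) = 0.0; Y(i, 0) = 0.0;
    for (int k = 1; k <= n_samples; k++) {
      long remaining = steps_per_sample;
      while (remaining > 0) {
        long h = remaining < gap ? remaining : gap;
        x += cx * step_len * h;
        y += cy * step_len * h;
        remaining -= h;
        gap -= h;
        if (gap == 0) {
          turn(b, dx, dy, cx, cy);
          if (p >= 1.0) gap = 1;
          else gap = 1 + (long)std::floor(std::log(unif_rand()) / lq);
        }
      }
      X(i, k) = x; Y(i, k) = y;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}

// Forward model for the ABC calibrator: same walk and RNG order as
// bprw_tracks_cpp with a shared speed, but accumulating the mean
// distance-from-origin per sample across cells instead of storing the
// tracks.  Returns a vector of length n_samples + 1 (t = 0 first).
// [[Rcpp::export]]
NumericVector bprw_mean_disp_cpp(int n, double speed, double b, double dx,
                                 double dy, double tau, double dt,
                                 int steps_per_sample, int n_samples) {
  double p = dt / tau;
  if (p > 1.0) p = 1.0;
  double lq = std::log1p(-p);
  NumericVector acc(n_samples + 1);
  for (int i = 0; i < n; i++) {
    double x = 0.0, y = 0.0;
    double cx, cy;
    turn(b, dx, dy, cx, cy);
    double step_len = speed * dt;
    long gap;
    if (p >= 1.0) gap = 1;
    else gap = 1 + (long)std::floor(std::log(unif_rand()) / lq);
    for (int k = 1; k <= n_samples; k++) {
      long remaining = steps_per_sample;
      while (remaining > 0) {
        long h = remaining < gap ? remaining : gap;
        x += cx * step_len * h;
        y += cy * step_len * h;
        remaining -= h;
        gap -= h;
        if (gap == 0) {
          turn(b, dx, dy, cx, cy);
          if (p >= 1.0) gap = 1;
          else gap = 1 + (long)std::floor(std::log(unif_rand()) / lq);
        }
      }
      acc[k] += std::sqrt(x * x + y * y);
    }
  }
  for (int k = 0; k <= n_samples; k++) acc[k] /= n;
  return acc;
}
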