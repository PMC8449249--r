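#include <Rcpp.h>
using namespace Rcpp;

NumericMatrix steady_solve_cpp(NumericMatrix sigma, IntegerMatrix dirichlet,
                               double sigma_bar, NumericMatrix lambda,
                               double D, double h, double tol,
                               int max_sweeps, double omega);

// cell phenotype states
enum { NORMOXIC = 0, HYPOXIC = 1, POSTHYPOXIC = 2, NECROTIC = 3 };

struct Pop {
  std::vector<double> x, y, dsred, gfp, cyc_clock, pers_clock, necro_clock,
      dirx, diry, pressure, sigma_loc;
  std::vector<int> state, switched, responder, reverted, ki67;
  size_t size() const { return x.size(); }
  void erase(size_t i) {
#define ER(v) v[i] = v.back(); v.pop_back();
    ER(x) ER(y) ER(dsred) ER(gfp) ER(cyc_clock) ER(pers_clock) ER(necro_clock)
    ER(dirx) ER(diry) ER(pressure) ER(sigma_loc)
    ER(state) ER(switched) ER(responder) ER(reverted) ER(ki67)
#undef ER
  }
};

static inline double bilinear(const NumericMatrix &f, double x, double y,
                              double h) {
  int ny = f.nrow(), nx = f.ncol();
  double gx = x / h - 0.5, gy = y / h - 0.5; // voxel centers at (j+.5)h
  int j0 = (int)std::floor(gx), i0 = (int)std::floor(gy);
  double fx = gx - j0, fy = gy - i0;
  if (j0 < 0) { j0 = 0; fx = 0; }
  if (i0 < 0) { i0 = 0; fy = 0; }
  int j1 = std::min(j0 + 1, nx - 1), i1 = std::min(i0 + 1, ny - 1);
  if (j0 > nx - 1) { j0 = j1 = nx - 1; fx = 0; }
  if (i0 > ny - 1) { i0 = i1 = ny - 1; fy = 0; }
  return f(i0, j0) * (1 - fx) * (1 - fy) + f(i0, j1) * fx * (1 - fy) +
         f(i1, j0) * (1 - fx) * fy + f(i1, j1) * fx * fy;
}

static inline void runit2e(double &ux, double &uy) {
  double th = 2.0 * M_PI * unif_rand();
  ux = std::cos(th); uy = std::sin(th);
}

// effective motility preset of a cell (speed, bias)
static inline void motility_of(const Pop &P, size_t i, double s_dsred,
                               double b_dsred, double s_gfp, double b_gfp,
                               double b_star, double &s, double &b) {
  if (P.state[i] == NECROTIC) { s = 0; b = 0; return; }
  bool migratory = (P.state[i] == HYPOXIC) ||
                   (P.state[i] == POSTHYPOXIC && !P.reverted[i]);
  if (migratory) {
    s = s_gfp;
    b = P.responder[i] ? b_star : b_gfp;
  } else {
    s = s_dsred;
    b = b_dsred;
  }
}

// Run the coupled tumor simulation: oxygen reaction-diffusion, phenotype
// switching with permanent fate mapping, fluorescence ODEs, Ki67 cycle,
// necrosis with lysis, adhesion-repulsion mechanics and biased persistent
// random-walk motility along the oxygen gradient.
// [[Rcpp::export]]
List run_engine_cpp(NumericVector x0, NumericVector y0, NumericMatrix sigma0,
                    IntegerMatrix dirichlet, List par) {
  // --- parameters -------------------------------------------------------
  const double L        = as<double>(par["domain_um"]);
  const double h        = as<double>(par["spacing_um"]);
  const double sigma_bar= as<double>(par["sigma_far"]);
  const double D        = as<double>(par["D"]);
  const double lambda_bg= as<double>(par["lambda_bg"]);
  const double r_uptake = as<double>(par["uptake_viable"]);
  const double necro_up = as<double>(par["uptake_necrotic_frac"]);
  const double sigma_H  = as<double>(par["sigma_H"]);
  const double sigma_T  = as<double>(par["sigma_T"]);
  const double Tp       = as<double>(par["Tp_min"]);      // < 0 means infinite
  const double Fr       = as<double>(par["Fr"]);
  const double b_star   = as<double>(par["b_star"]);
  const double s_dsred  = as<double>(par["s_dsred"]);
  const double b_dsred  = as<double>(par["b_dsred"]);
  const double s_gfp    = as<double>(par["s_gfp"]);
  const double b_gfp    = as<double>(par["b_gfp"]);
  const double tau      = as<double>(par["tau"]);
  const double radius   = as<double>(par["cell_radius"]);
  const double c_rep    = as<double>(par["repulsion"]);
  const double c_adh    = as<double>(par["adhesion"]);
  const double adh_f    = as<double>(par["adhesion_factor"]);
  const double alpha0   = as<double>(par["alpha0"]);
  const double beta0    = as<double>(par["beta0"]);
  const double alpha1   = as<double>(par["alpha1"]);
  const double beta1    = as<double>(par["beta1"]);
  const double ki_rate  = as<double>(par["ki67_entry_rate"]);
  const double ki_dur   = as<double>(par["ki67_duration"]);
  const double lysis    = as<double>(par["lysis_time"]);
  const bool   feedback = as<bool>(par["pressure_feedback"]);
  const double p_thresh = as<double>(par["pressure_threshold"]);
  const double dt_phen  = as<double>(par["dt_phenotype"]);
  const double dt_mech  = as<double>(par["dt_mechanics"]);
  const double end_time = as<double>(par["end_time_min"]);
  const double snap_int = as<double>(par["snapshot_interval_min"]);
  const int    n_max    = as<int>(par["max_cells"]);

  const int ny = sigma0.nrow(), nx = sigma0.ncol();
  NumericMatrix sigma(clone(sigma0));
  const double cell_area_frac = M_PI * radius * radius / (h * h);

  // pressure normalised so one neighbour at the adhesion-repulsion
  // equilibrium spacing contributes 1
  const double x_eq =
      (std::sqrt(c_rep) - std::sqrt(c_adh)) /
      (std::sqrt(c_rep) - std::sqrt(c_adh) / adh_f);
  const double p_norm = (1.0 - x_eq) * (1.0 - x_eq);

  // --- population -------------------------------------------------------
  Pop P;
  size_t n0 = x0.size();
  for (size_t i = 0; i < n0; i++) {
    P.x.push_back(x0[i]); P.y.push_back(y0[i]);
    P.state.push_back(NORMOXIC); P.switched.push_back(0);
    P.responder.push_back(0); P.reverted.push_back(0);
    P.dsred.push_back(1.0); P.gfp.push_back(0.0);
    // seed the cycle near its well-oxygenated steady state
    int k = unif_rand() < ki_dur / (ki_dur + 1.0 / ki_rate) ? 1 : 0;
    P.ki67.push_back(k);
    P.cyc_clock.push_back(k ? unif_rand() * ki_dur : 0.0);
    P.pers_clock.push_back(0.0); P.necro_clock.push_back(0.0);
    double ux, uy; runit2e(ux, uy);
    P.dirx.push_back(ux); P.diry.push_back(uy);
    P.pressure.push_back(0.0); P.sigma_loc.push_back(sigma_bar);
  }

  // --- outputs ----------------------------------------------------------
  List snapshots;
  std::vector<double> t_log, nv_log, nn_log, nsw_log, div_log, lys_log;
  long total_div = 0, total_lys = 0;

  int n_phen = (int)std::round(end_time / dt_phen);
  int n_sub_mech = std::max(1, (int)std::round(dt_phen / dt_mech));
  int snap_every = std::max(1, (int)std::round(snap_int / dt_phen));

  NumericMatrix lambda(ny, nx), gradx(ny, nx), grady(ny, nx);

  // spatial hash for mechanics
  double bin = 2.0 * radius * adh_f * 1.05;
  int nbx = std::max(1, (int)(L / bin)), nby = nbx;
  std::vector<std::vector<int>> bins((size_t)nbx * nby);

  auto take_snapshot = [&](double t_now) {
    size_t n = P.size();
    NumericVector sx(n), sy(n), sd(n), sg(n), spc(n), ssl(n), spr(n);
    IntegerVector sst(n), ssw(n), sre(n), ski(n), srv(n);
    for (size_t i = 0; i < n; i++) {
      sx[i] = P.x[i]; sy[i] = P.y[i]; sd[i] = P.dsred[i]; sg[i] = P.gfp[i];
      spc[i] = P.pers_clock[i]; ssl[i] = bilinear(sigma, P.x[i], P.y[i], h);
      spr[i] = P.pressure[i];
      sst[i] = P.state[i]; ssw[i] = P.switched[i]; sre[i] = P.responder[i];
      ski[i] = P.ki67[i]; srv[i] = P.reverted[i];
    }
    snapshots.push_back(List::create(
        _["time_min"] = t_now, _["x_um"] = sx, _["y_um"] = sy,
        _["state"] = sst, _["switched"] = ssw, _["DsRed"] = sd,
        _["GFP"] = sg, _["Ki67"] = ski, _["responder"] = sre,
        _["reverted"] = srv, _["persistence_clock_min"] = spc,
        _["sigma_local"] = ssl, _["pressure"] = spr,
        _["sigma_field"] = clone(sigma)));
  };

  take_snapshot(0.0);

  for (int step = 1; step <= n_phen; step++) {
    double t_now = step * dt_phen;
    size_t n = P.size();
    if ((int)n > n_max)
      stop("cell count exceeded max_cells (%d) at t = %.0f min", n_max, t_now);

    // ---- oxygen uptake map and diffusion ------------------------------
    std::fill(lambda.begin(), lambda.end(), lambda_bg);
    for (size_t i = 0; i < n; i++) {
      int j = std::min(nx - 1, std::max(0, (int)(P.x[i] / h)));
      int ii = std::min(ny - 1, std::max(0, (int)(P.y[i] / h)));
      double u = (P.state[i] == NECROTIC) ? r_uptake * necro_up : r_uptake;
      lambda(ii, j) += u * cell_area_frac;
    }
    // oxygen equilibrates within seconds at these scales: quasi-static
    // steady solve each phenotype step, warm-started from the last field
    sigma = steady_solve_cpp(sigma, dirichlet, sigma_bar, lambda, D, h,
                             1e-4, 5000, 1.9);

    // ---- gradient field (central differences) -------------------------
    for (int i = 0; i < ny; i++)
      for (int j = 0; j < nx; j++) {
        int jm = std::max(0, j - 1), jp = std::min(nx - 1, j + 1);
        int im = std::max(0, i - 1), ip = std::min(ny - 1, i + 1);
        gradx(i, j) = (sigma(i, jp) - sigma(i, jm)) / ((jp - jm) * h);
        grady(i, j) = (sigma(ip, j) - sigma(im, j)) / ((ip - im) * h);
      }

    // ---- slow per-cell processes (phenotype, fluorescence, cycle) -----
    long divisions = 0, lysed = 0;
    std::vector<size_t> to_remove;
    size_t n_before = P.size();
    for (size_t i = 0; i < n_before; i++) {
      double sl = bilinear(sigma, P.x[i], P.y[i], h);
      P.sigma_loc[i] = sl;
      if (P.state[i] == NECROTIC) {
        P.necro_clock[i] += dt_phen;
        if (lysis >= 0 && P.necro_clock[i] > lysis) to_remove.push_back(i);
      } else if (sl < sigma_T) {
        P.state[i] = NECROTIC; P.ki67[i] = 0; P.necro_clock[i] = 0.0;
        if (!P.switched[i]) { // necrosis below sigma_T implies hypoxia passed
          P.switched[i] = 1; P.responder[i] = unif_rand() < Fr ? 1 : 0;
        }
      } else if (sl < sigma_H) {
        if (!P.switched[i]) { // first hypoxic exposure: permanent switch
          P.switched[i] = 1;
          P.responder[i] = unif_rand() < Fr ? 1 : 0;
        }
        if (P.state[i] != HYPOXIC) { // entering (or re-entering) hypoxia
          P.state[i] = HYPOXIC; P.pers_clock[i] = 0.0; P.reverted[i] = 0;
        }
      } else { // oxygenated
        if (P.state[i] == HYPOXIC) { P.state[i] = POSTHYPOXIC; P.pers_clock[i] = 0.0; }
        else if (P.state[i] == POSTHYPOXIC) P.pers_clock[i] += dt_phen;
        if (P.state[i] == POSTHYPOXIC && Tp >= 0 && P.pers_clock[i] >= Tp)
          P.reverted[i] = 1;
      }

      // fluorescence: exact exponential update of the two protein ODEs
      if (P.state[i] != NECROTIC || true) { // proteins persist in necrotic debris
        if (P.switched[i]) { // G = (0, 1)
          P.dsred[i] *= std::exp(-beta0 * dt_phen);
          P.gfp[i] = 1.0 - (1.0 - P.gfp[i]) * std::exp(-alpha1 * dt_phen);
        } else {             // G = (1, 0)
          P.dsred[i] = 1.0 - (1.0 - P.dsred[i]) * std::exp(-alpha0 * dt_phen);
          P.gfp[i] *= std::exp(-beta1 * dt_phen);
        }
      }

      // Ki67 cycle with oxygen-scaled entry rate
      if (P.state[i] != NECROTIC) {
        if (!P.ki67[i]) {
          double rate = ki_rate * std::min(std::max(sl, 0.0) / sigma_bar, 1.0);
          if (unif_rand() < -std::expm1(-rate * dt_phen)) {
            P.ki67[i] = 1; P.cyc_clock[i] = 0.0;
          }
        } else {
          P.cyc_clock[i] += dt_phen;
          if (P.cyc_clock[i] >= ki_dur) {
            bool blocked = feedback && P.pressure[i] > p_thresh;
            if (!blocked && (int)P.size() < n_max) {
              double ux, uy; runit2e(ux, uy);
              P.x.push_back(std::min(L - radius, std::max(radius, P.x[i] + radius * ux)));
              P.y.push_back(std::min(L - radius, std::max(radius, P.y[i] + radius * uy)));
              P.state.push_back(P.state[i]); P.switched.push_back(P.switched[i]);
              P.responder.push_back(P.responder[i]);
              P.reverted.push_back(P.reverted[i]);
              P.dsred.push_back(P.dsred[i]); P.gfp.push_back(P.gfp[i]);
              P.ki67.push_back(0); P.cyc_clock.push_back(0.0);
              P.pers_clock.push_back(P.pers_clock[i]);
              P.necro_clock.push_back(0.0);
              double vx, vy; runit2e(vx, vy);
              P.dirx.push_back(vx); P.diry.push_back(vy);
              P.pressure.push_back(0.0); P.sigma_loc.push_back(sl);
              P.ki67[i] = 0; P.cyc_clock[i] = 0.0;
              divisions++;
            } // else: hold at end of Ki67+ phase until allowed
          }
        }
      }
    }
    // remove lysed cells (descending order keeps swap-erase indices valid)
    for (auto it = to_remove.rbegin(); it != to_remove.rend(); ++it) P.erase(*it);
    lysed = to_remove.size();
    total_div += divisions; total_lys += lysed;

    // ---- mechanics + motility substeps --------------------------------
    n = P.size();
    std::vector<double> vx(n), vy(n);
    double p_turn = dt_mech / tau;
    for (int ms = 0; ms < n_sub_mech; ms++) {
      for (auto &b : bins) b.clear();
      for (size_t i = 0; i < n; i++) {
        int bx = std::min(nbx - 1, std::max(0, (int)(P.x[i] / bin)));
        int by = std::min(nby - 1, std::max(0, (int)(P.y[i] / bin)));
        bins[(size_t)by * nbx + bx].push_back((int)i);
      }
      std::fill(vx.begin(), vx.end(), 0.0);
      std::fill(vy.begin(), vy.end(), 0.0);
      for (size_t i = 0; i < n; i++) P.pressure[i] = 0.0;
      double r_int = 2.0 * radius * adh_f;
      for (size_t i = 0; i < n; i++) {
        int bx = std::min(nbx - 1, std::max(0, (int)(P.x[i] / bin)));
        int by = std::min(nby - 1, std::max(0, (int)(P.y[i] / bin)));
        for (int dby = -1; dby <= 1; dby++)
          for (int dbx = -1; dbx <= 1; dbx++) {
            int cx = bx + dbx, cy = by + dby;
            if (cx < 0 || cy < 0 || cx >= nbx || cy >= nby) continue;
            for (int jj : bins[(size_t)cy * nbx + cx]) {
              size_t j = (size_t)jj;
              if (j <= i) continue;
              double ddx = P.x[j] - P.x[i], ddy = P.y[j] - P.y[i];
              double d2 = ddx * ddx + ddy * ddy;
              if (d2 >= r_int * r_int || d2 < 1e-12) continue;
              double d = std::sqrt(d2);
              double ex = ddx / d, ey = ddy / d;
              double Rsum = 2.0 * radius;
              double f = 0.0;
              if (d < Rsum) {
                double o = 1.0 - d / Rsum;
                f -= c_rep * o * o; // repulsion: push apart
                double pr = o * o / p_norm;
                P.pressure[i] += pr; P.pressure[j] += pr;
              }
              double oa = 1.0 - d / r_int;
              f += c_adh * oa * oa;   // adhesion: pull together
              vx[i] += f * ex; vy[i] += f * ey;
              vx[j] -= f * ex; vy[j] -= f * ey;
            }
          }
      }
      // motility term + integration
      for (size_t i = 0; i < n; i++) {
        if (P.state[i] != NECROTIC) {
          double s_eff, b_eff;
          motility_of(P, i, s_dsred, b_dsred, s_gfp, b_gfp, b_star, s_eff, b_eff);
          if (unif_rand() < p_turn) {
            double gx = bilinear(gradx, P.x[i], P.y[i], h);
            double gy = bilinear(grady, P.x[i], P.y[i], h);
            double gn = std::sqrt(gx * gx + gy * gy);
            double dxp = 0.0, dyp = 0.0;
            if (gn > 1e-12) {
              dxp = gx / gn; dyp = gy / gn;
              if (feedback && P.pressure[i] > p_thresh) { dxp = -dxp; dyp = -dyp; }
            }
            for (;;) {
              double ux, uy; runit2e(ux, uy);
              double wx = (1.0 - b_eff) * ux + b_eff * dxp;
              double wy = (1.0 - b_eff) * uy + b_eff * dyp;
              double wn = std::sqrt(wx * wx + wy * wy);
              if (wn > 1e-12) { P.dirx[i] = wx / wn; P.diry[i] = wy / wn; break; }
            }
          }
          vx[i] += s_eff * P.dirx[i];
          vy[i] += s_eff * P.diry[i];
        }
        P.x[i] = std::min(L - radius, std::max(radius, P.x[i] + vx[i] * dt_mech));
        P.y[i] = std::min(L - radius, std::max(radius, P.y[i] + vy[i] * dt_mech));
      }
    }

    // ---- logging / snapshots ------------------------------------------
    int nv = 0, nn = 0, nsw = 0;
    for (size_t i = 0; i < P.size(); i++) {
      if (P.state[i] == NECROTIC) nn++; else nv++;
      if (P.switched[i]) nsw++;
    }
    t_log.push_back(t_now); nv_log.push_back(nv); nn_log.push_back(nn);
    nsw_log.push_back(nsw); div_log.push_back((double)divisions);
    lys_log.push_back((double)lysed);
    if (step % snap_every == 0 || step == n_phen) take_snapshot(t_now);
    if (step % 50 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
      _["snapshots"] = snapshots,
      _["counts"] = DataFrame::create(
          _["time_min"] = t_log, _["n_viable"] = nv_log,
          _["n_necrotic"] = nn_log, _["n_switched"] = nsw_log,
          _["divisions"] = div_log, _["lysed"] = lys_log),
      _["total_divisions"] = (double)total_div,
      _["total_lysed"] = (double)total_lys,
      _["sigma_final"] = sigma);
}
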