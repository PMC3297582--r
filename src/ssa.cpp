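#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Global core-promoter activity g(t): Gaussian rise to 1 at t0, then a
// double-exponential decline whose slow component produces the late shoulder.
static inline double g_activity(double t, double t0, const double* gp) {
  // gp: floor0, rise_width, floor_late, tau_fast, tau_slow, shoulder
  if (t < t0) {
    double z = (t - t0) / gp[1];
    return gp[0] + (1.0 - gp[0]) * std::exp(-z * z);
  }
  double u = t - t0;
  double mix = (1.0 - gp[5]) * std::exp(-u / gp[3]) + gp[5] * std::exp(-u / gp[4]);
  return gp[2] + (1.0 - gp[2]) * mix;
}

// spo0A transcription drive h(t): rises like g(t), maintained at 1 after t0.
static inline double h_drive(double t, double t0, const double* hp) {
  // hp: floor0, rise_width
  if (t >= t0) return 1.0;
  double z = (t - t0) / hp[1];
  return hp[0] + (1.0 - hp[0]) * std::exp(-z * z);
}

// The simulation keeps per-reaction propensity parts that do not depend on
// time cached, and refreshes only the reactions whose inputs changed when a
// reaction fires.  Total propensity is assembled each step as
//   A(t) = S_mass + g(t) * T_tx + h(t) * C_drive
// where S_mass sums the (time-independent) mass-action propensities, T_tx
// sums the occupancy factors of the transcription channels and C_drive sums
// the zero-order production constants.

// [[Rcpp::export(name = ".ssa_run_cpp")]]
List ssa_run_cpp(IntegerVector init, IntegerMatrix stoich, IntegerVector rtype,
                 NumericVector rconst, IntegerVector s1, IntegerVector s2,
                 List tx_meta, List drive, double t_end, double dt_max,
                 double grid_dt, bool record_events) {
  const int n_sp = init.size();
  const int n_rx = rtype.size();

  const double t0 = as<double>(drive["t0"]);
  NumericVector gshape = drive["g"];
  NumericVector hshape = drive["h"];
  const double alpha = as<double>(drive["alpha"]);
  const double rho_rok = as<double>(drive["rho_rok"]);
  const double rho_r = as<double>(drive["rho_R"]);
  const bool all_or_none = as<bool>(drive["all_or_none"]);
  const int n_a_sites = as<int>(drive["n_a_sites"]);
  const double* gp = gshape.begin();
  const double* hp = hshape.begin();

  double pow_a[4], pow_rok[5], pow_r[5];
  for (int i = 0; i < 4; ++i) pow_a[i] = std::pow(alpha, i);
  for (int i = 0; i < 5; ++i) pow_rok[i] = std::pow(rho_rok, i);
  for (int i = 0; i < 5; ++i) pow_r[i] = std::pow(rho_r, i);

  std::vector<std::vector<int>> txA(n_rx), txRok(n_rx), txR(n_rx);
  for (int r = 0; r < n_rx; ++r) {
    if (rtype[r] == 3) {
      List m = tx_meta[r];
      txA[r] = as<std::vector<int>>(m["iA"]);
      txRok[r] = as<std::vector<int>>(m["iRok"]);
      txR[r] = as<std::vector<int>>(m["iR"]);
    }
  }

  // sparse stoichiometry per reaction
  std::vector<std::vector<std::pair<int, int>>> delta(n_rx);
  for (int r = 0; r < n_rx; ++r)
    for (int i = 0; i < n_sp; ++i)
      if (stoich(r, i) != 0) delta[r].push_back({i, stoich(r, i)});

  // dependency lists: which reactions must be refreshed when species i changes
  std::vector<std::vector<int>> dep(n_sp);
  for (int r = 0; r < n_rx; ++r) {
    switch (rtype[r]) {
    case 1: dep[s1[r]].push_back(r); break;
    case 2: dep[s1[r]].push_back(r); dep[s2[r]].push_back(r); break;
    case 3:
      for (int k : txA[r]) dep[k].push_back(r);
      for (int k : txRok[r]) dep[k].push_back(r);
      for (int k : txR[r]) dep[k].push_back(r);
      break;
    default: break;
    }
  }

  std::vector<long long> x(n_sp);
  for (int i = 0; i < n_sp; ++i) x[i] = init[i];

  // cached per-reaction values: mass-action propensity for types 1/2,
  // occupancy factor (incl. rconst) for type 3, rconst for type 0
  std::vector<double> part(n_rx, 0.0);
  double S_mass = 0.0, T_tx = 0.0, C_drive = 0.0;
  auto eval_part = [&](int r) -> double {
    switch (rtype[r]) {
    case 0: return rconst[r];
    case 1: return rconst[r] * (double)x[s1[r]];
    case 2: return rconst[r] * (double)x[s1[r]] * (double)x[s2[r]];
    case 3: {
      int nA = 0, nRok = 0, nR = 0;
      for (int k : txA[r]) nA += (int)x[k];
      for (int k : txRok[r]) nRok += (int)x[k];
      for (int k : txR[r]) nR += (int)x[k];
      double act = all_or_none ? (nA == n_a_sites ? pow_a[n_a_sites] : 1.0)
                               : pow_a[nA];
      return rconst[r] * act * pow_rok[nRok] * pow_r[nR];
    }
    default: return 0.0;
    }
  };
  auto rebuild_sums = [&]() {
    S_mass = T_tx = C_drive = 0.0;
    for (int r = 0; r < n_rx; ++r) {
      part[r] = eval_part(r);
      if (part[r] < 0.0 || !std::isfinite(part[r]))
        stop("propensity of reaction %d is negative or non-finite", r + 1);
      if (rtype[r] == 0) C_drive += part[r];
      else if (rtype[r] == 3) T_tx += part[r];
      else S_mass += part[r];
    }
  };
  rebuild_sums();

  const int n_grid = (int)std::floor(t_end / grid_dt + 1e-9) + 1;
  IntegerMatrix snaps(n_grid, n_sp);
  NumericVector grid_times(n_grid);
  for (int i = 0; i < n_grid; ++i) grid_times[i] = i * grid_dt;
  int next_grid = 0;

  std::vector<std::vector<double>> tx_times(n_rx);
  std::vector<double> ev_t;
  std::vector<int> ev_id;
  std::vector<int> touched;
  touched.reserve(16);

  double t = 0.0;
  long long n_events = 0;
  RNGScope scope;

  while (t < t_end) {
    double g_now = g_activity(t, t0, gp);
    double h_now = h_drive(t, t0, hp);
    double atot = S_mass + g_now * T_tx + h_now * C_drive;

    double tau;
    bool fire = false;
    if (atot > 0.0) {
      tau = exp_rand() / atot;
      if (tau > dt_max) tau = dt_max; else fire = true;
    } else {
      tau = dt_max;
    }
    double t_new = t + tau;
    if (t_new > t_end) { t_new = t_end; fire = false; }

    // snapshots carry the pre-event state over (t, t_new]
    while (next_grid < n_grid && grid_times[next_grid] <= t_new + 1e-12) {
      for (int i = 0; i < n_sp; ++i) snaps(next_grid, i) = (int)x[i];
      ++next_grid;
    }
    t = t_new;
    if (!fire) continue;

    // select reaction proportionally to current propensities
    double u = unif_rand() * atot;
    int r = -1;
    double cum = 0.0;
    for (int k = 0; k < n_rx; ++k) {
      double ak = (rtype[k] == 0) ? part[k] * h_now
                : (rtype[k] == 3) ? part[k] * g_now : part[k];
      cum += ak;
      if (u <= cum) { r = k; break; }
    }
    if (r < 0) {  // floating-point slack: take the last reaction with mass
      for (int k = n_rx - 1; k >= 0; --k)
        if (part[k] > 0.0) { r = k; break; }
      if (r < 0) continue;
    }

    touched.clear();
    for (auto& pr : delta[r]) {
      x[pr.first] += pr.second;
      if (x[pr.first] < 0)
        stop("species %d went negative after reaction %d", pr.first + 1, r + 1);
      for (int rr : dep[pr.first]) touched.push_back(rr);
    }
    for (int rr : touched) {
      double neu = eval_part(rr);
      if (neu < 0.0 || !std::isfinite(neu))
        stop("propensity of reaction %d is negative or non-finite", rr + 1);
      double old = part[rr];
      if (neu == old) continue;
      part[rr] = neu;
      if (rtype[rr] == 3) T_tx += neu - old; else S_mass += neu - old;
    }
    ++n_events;
    if ((n_events & 0x3FFF) == 0) rebuild_sums();  // curb fp drift
    if (rtype[r] == 3) tx_times[r].push_back(t);
    if (record_events) { ev_t.push_back(t); ev_id.push_back(r + 1); }
  }

  while (next_grid < n_grid) {
    for (int i = 0; i < n_sp; ++i) snaps(next_grid, i) = (int)x[i];
    ++next_grid;
  }

  List tx_out(n_rx);
  for (int r = 0; r < n_rx; ++r) tx_out[r] = wrap(tx_times[r]);

  List out = List::create(
    _["grid_times"] = grid_times, _["snapshots"] = snaps,
    _["tx_times"] = tx_out, _["n_events"] = (double)n_events);
  if (record_events) {
    out["event_times"] = wrap(ev_t);
    out["event_ids"] = wrap(ev_id);
  }
  return out;
}

// Deterministic evaluation of g(t) / h(t) on a time grid (shared with the R
// side so the mean-field oracle and the SSA use identical drive functions).
// [[Rcpp::export(name = ".drive_eval_cpp")]]
NumericMatrix drive_eval_cpp(NumericVector times, double t0, NumericVector gshape,
                             NumericVector hshape) {
  NumericMatrix out(times.size(), 2);
  for (int i = 0; i < times.size(); ++i) {
    out(i, 0) = g_activity(times[i], t0, gshape.begin());
    out(i, 1) = h_drive(times[i], t0, hshape.begin());
  }
  return out;
}
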