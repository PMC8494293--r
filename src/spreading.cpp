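#include <Rcpp.h>
using namespace Rcpp;

// Event-driven continuous-time simulation of sliding clamps on a 1D
// lattice. Clamps are injected at the parS site (Poisson, rate k_load),
// hop left/right at rate D each (1-bp steps), and unload at rate
// k_off_eff. Roadblocks and window boundaries reflect (blocked hop = null
// event, which keeps the jump chain exact) or absorb (clamp removed).
// With `exclusion`, hops or loads into an occupied site are null events.
//
// Occupancy is accumulated as time-weighted per-site dwell after burn_in,
// using lazy per-site flushing so each event costs O(1).
//
// site codes: 0 free lattice, 1 reflecting roadblock, 2 absorbing roadblock

// [[Rcpp::export(name = ".spread_sim")]]
List spread_sim(int L, int parS, double D, double k_load, double k_off,
                IntegerVector site_code, int bleft_absorb, int bright_absorb,
                bool exclusion, double t_end, double burn_in,
                int n_initial) {
  if (L < 3 || parS < 0 || parS >= L) stop("bad lattice geometry");
  if (burn_in < 0 || burn_in >= t_end) stop("need 0 <= burn_in < t_end");
  if (site_code.size() != L) stop("site_code must have length L");
  if (site_code[parS] != 0) stop("parS must not be a roadblock site");

  std::vector<int> pos;                    // positions of live clamps
  pos.reserve(1024);
  std::vector<int> nocc(L, 0);             // clamps per site
  std::vector<double> acc(L, 0.0), last(L, 0.0);
  double loaded = 0.0, unloaded = 0.0, absorbed = 0.0, blocked_loads = 0.0;

  for (int k = 0; k < n_initial; ++k) {
    if (exclusion && nocc[parS] > 0) { blocked_loads += 1.0; continue; }
    pos.push_back(parS); nocc[parS] += 1;
  }

  auto flush = [&](int x, double t) {
    double lo = std::max(last[x], burn_in);
    if (t > lo) acc[x] += nocc[x] * (t - lo);
    last[x] = t;
  };

  const double per_clamp = 2.0 * D + k_off;
  double t = 0.0;

  while (t < t_end) {
    double rtot = k_load + per_clamp * pos.size();
    if (rtot <= 0.0) break;
    double dt = R::exp_rand() / rtot;
    double tn = t + dt;
    if (tn >= t_end) { t = t_end; break; }
    t = tn;

    double u = R::unif_rand() * rtot;
    if (u < k_load) {                      // load at parS
      if (exclusion && nocc[parS] > 0) { blocked_loads += 1.0; continue; }
      flush(parS, t);
      pos.push_back(parS); nocc[parS] += 1; loaded += 1.0;
      continue;
    }
    // pick a clamp and an action
    double v = u - k_load;
    int idx = (int)(v / per_clamp);
    if (idx >= (int)pos.size()) idx = pos.size() - 1;
    double w = v - idx * per_clamp;
    int x = pos[idx];

    auto remove_clamp = [&](double &counter) {
      flush(x, t);
      nocc[x] -= 1;
      pos[idx] = pos.back(); pos.pop_back();
      counter += 1.0;
    };

    if (w < k_off) { remove_clamp(unloaded); continue; }
    int dir = (w < k_off + D) ? -1 : 1;
    int nx = x + dir;
    if (nx < 0) {                          // left boundary
      if (bleft_absorb) remove_clamp(absorbed);
      continue;                            // reflect = null event
    }
    if (nx >= L) {
      if (bright_absorb) remove_clamp(absorbed);
      continue;
    }
    int code = site_code[nx];
    if (code == 1) continue;               // reflecting roadblock
    if (code == 2) { remove_clamp(absorbed); continue; }
    if (exclusion && nocc[nx] > 0) continue;
    flush(x, t); flush(nx, t);
    nocc[x] -= 1; nocc[nx] += 1; pos[idx] = nx;
  }

  for (int xx = 0; xx < L; ++xx) flush(xx, t_end);
  double span = t_end - burn_in;
  NumericVector occ(L);
  for (int xx = 0; xx < L; ++xx) occ[xx] = acc[xx] / span;

  return List::create(
    _["occupancy"] = occ,
    _["terminal"] = IntegerVector(pos.begin(), pos.end()),
    _["loaded"] = loaded, _["unloaded"] = unloaded,
    _["absorbed"] = absorbed, _["blocked_loads"] = blocked_loads);
}
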