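#include <Rcpp.h>
using namespace Rcpp;

// Exact stochastic simulation, direct method.
//
// State: integer copy numbers x. Propensity of reaction j:
//   a_j = rate_j * prod_i x_i * (x_i - 1) * ... * (x_i - s_ij + 1)
// (mass-action combinatorics; rates are already in copy-number units).
// Time-averaged species means are accumulated after burn_in, split into
// `nbatch` equal-length batches so callers can estimate Monte Carlo
// standard errors by batch means. Uses R's RNG: set.seed() upstream
// makes runs reproducible.

// [[Rcpp::export(name = ".ssa_direct")]]
List ssa_direct(IntegerVector x0, IntegerMatrix Sr, IntegerMatrix Sp,
                NumericVector rate, double t_end, double burn_in,
                IntegerVector hydro, int max_store, int nbatch) {
  const int ns = x0.size();
  const int nr = rate.size();
  if (Sr.nrow() != ns || Sr.ncol() != nr || Sp.nrow() != ns || Sp.ncol() != nr)
    stop("stoichiometry dimensions do not match species/reactions");
  if (burn_in < 0 || burn_in >= t_end) stop("need 0 <= burn_in < t_end");
  if (nbatch < 1) nbatch = 1;

  std::vector<double> x(ns);
  for (int i = 0; i < ns; ++i) x[i] = x0[i];

  std::vector<bool> is_hydro(nr, false);
  for (int k = 0; k < hydro.size(); ++k) {
    int j = hydro[k] - 1;  // 1-based from R
    if (j < 0 || j >= nr) stop("hydrolysis reaction index out of range");
    is_hydro[j] = true;
  }

  std::vector<double> a(nr), fired_total(nr, 0.0), fired_post(nr, 0.0);
  std::vector<double> tavg(ns, 0.0);
  NumericMatrix batch(nbatch, ns);
  const double batch_len = (t_end - burn_in) / nbatch;

  std::vector<double> ev_t;
  std::vector<int> ev_r;
  if (max_store > 0) { ev_t.reserve(std::min(max_store, 1 << 20));
                       ev_r.reserve(std::min(max_store, 1 << 20)); }

  double t = 0.0, hydro_post = 0.0;
  bool truncated = false;
  long long n_events = 0;

  // accumulate x * dt over [t0, t1) into tavg and the batch rows
  auto accumulate = [&](double t0, double t1) {
    double lo = std::max(t0, burn_in);
    if (t1 <= lo) return;
    for (int i = 0; i < ns; ++i) tavg[i] += x[i] * (t1 - lo);
    // split across batch boundaries
    double s = lo;
    while (s < t1) {
      int b = (int)((s - burn_in) / batch_len);
      if (b >= nbatch) b = nbatch - 1;
      double bend = burn_in + (b + 1) * batch_len;
      double e = std::min(t1, bend);
      for (int i = 0; i < ns; ++i) batch(b, i) += x[i] * (e - s);
      if (e <= s) break;
      s = e;
    }
  };

  while (t < t_end) {
    double atot = 0.0;
    for (int j = 0; j < nr; ++j) {
      double aj = rate[j];
      for (int i = 0; i < ns && aj > 0; ++i) {
        int s = Sr(i, j);
        for (int k = 0; k < s; ++k) aj *= std::max(x[i] - k, 0.0);
      }
      a[j] = aj;
      atot += aj;
      if (!R_finite(atot)) stop("propensity overflow");
    }
    if (atot <= 0.0) { accumulate(t, t_end); t = t_end; break; }

    double dt = R::exp_rand() / atot;
    double t_next = t + dt;
    if (t_next >= t_end) { accumulate(t, t_end); t = t_end; break; }

    // choose reaction
    double u = R::unif_rand() * atot, c = 0.0;
    int j = nr - 1;
    for (int k = 0; k < nr; ++k) { c += a[k]; if (u <= c) { j = k; break; } }

    accumulate(t, t_next);
    t = t_next;
    for (int i = 0; i < ns; ++i) x[i] += Sp(i, j) - Sr(i, j);
    fired_total[j] += 1.0;
    if (t > burn_in) {
      fired_post[j] += 1.0;
      if (is_hydro[j]) hydro_post += 1.0;
    }
    ++n_events;
    if (max_store > 0) {
      if ((int)ev_t.size() < max_store) { ev_t.push_back(t); ev_r.push_back(j + 1); }
      else truncated = true;
    }
  }

  double span = t_end - burn_in;
  NumericVector tavg_out(ns);
  for (int i = 0; i < ns; ++i) tavg_out[i] = tavg[i] / span;
  for (int b = 0; b < nbatch; ++b)
    for (int i = 0; i < ns; ++i) batch(b, i) /= batch_len;

  IntegerVector xfin(ns);
  for (int i = 0; i < ns; ++i) xfin[i] = (int)std::lround(x[i]);

  return List::create(
    _["times"] = NumericVector(ev_t.begin(), ev_t.end()),
    _["reaction"] = IntegerVector(ev_r.begin(), ev_r.end()),
    _["final"] = xfin,
    _["fired_total"] = NumericVector(fired_total.begin(), fired_total.end()),
    _["fired_post"] = NumericVector(fired_post.begin(), fired_post.end()),
    _["tavg"] = tavg_out,
    _["batch"] = batch,
    _["hydrolysis_post"] = hydro_post,
    _["n_events"] = (double)n_events,
    _["truncated"] = truncated);
}
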