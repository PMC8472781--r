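#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// falling factorial n (n-1) ... (n-nu+1); 0 when n < nu
static inline double ffact(double n, int nu) {
  double r = 1.0;
  for (int i = 0; i < nu; ++i) {
    double f = n - i;
    if (f <= 0.0) return 0.0;
    r *= f;
  }
  return r;
}

// Gillespie direct method on a compiled network.
//
// nu:  (D x m) educt stoichiometries per reaction direction
// dS:  (D x m) applied molecule-number changes (zeroed on chemostatted
//      species, so clamps are re-imposed for free)
// kV:  per-direction propensity prefactor k * V^(1 - sum nu)
// init: molecule counts at t0
//
// Propensities are refreshed through a species -> dependent-direction graph
// after each event; the total a0 is maintained incrementally and refreshed
// in full periodically to keep float drift negligible.  The waiting time is
// Exponential(a0), the event is chosen with probability w/a0.
//
// Stops after n_steps events, at t_max, or in an absorbing state (a0 = 0).
// tail_frac > 0 accumulates the time-weighted mean of the counts over the
// final ceil(tail_frac * n_steps) events.  record_stride > 0 stores count
// snapshots every record_stride events; record_events stores the full
// (time, direction) event log.
// [[Rcpp::export]]
List ssa_core(IntegerMatrix nu, IntegerMatrix dS, NumericVector kV,
              NumericVector init, double t0, int n_steps, double t_max,
              double tail_frac, int record_stride, bool record_events) {
  const int D = nu.nrow(), m = nu.ncol();
  std::vector<double> n(m);
  for (int i = 0; i < m; ++i) n[i] = init[i];

  // sparse educt and change lists per direction; dependency graph per species
  std::vector<std::vector<std::pair<int, int> > > ed(D), ch(D);
  std::vector<std::vector<int> > dep(m);
  for (int d = 0; d < D; ++d) {
    for (int i = 0; i < m; ++i) {
      if (nu(d, i) > 0) { ed[d].push_back(std::make_pair(i, nu(d, i))); dep[i].push_back(d); }
      if (dS(d, i) != 0) ch[d].push_back(std::make_pair(i, dS(d, i)));
    }
  }

  std::vector<double> w(D, 0.0);
  std::vector<long long> stamp(D, -1);
  double a0 = 0.0;
  for (int d = 0; d < D; ++d) {
    double wd = kV[d];
    for (size_t j = 0; j < ed[d].size(); ++j)
      wd *= ffact(n[ed[d][j].first], ed[d][j].second);
    w[d] = wd;
    a0 += wd;
  }

  double t = t0;
  long long n_done = 0;
  bool absorbed = false, hit_tmax = false;

  long long tail_len = (tail_frac > 0.0)
    ? (long long)std::ceil(tail_frac * (double)n_steps) : 0;
  long long tail_start = (long long)n_steps - tail_len;
  std::vector<double> tail_sum(m, 0.0);
  double tail_time = 0.0;

  std::vector<double> snap_t, snap_n, ev_t;
  std::vector<int> ev_d;
  if (record_stride > 0) {
    snap_t.reserve(n_steps / record_stride + 2);
    snap_n.reserve(((size_t)n_steps / record_stride + 2) * m);
  }
  if (record_events) { ev_t.reserve(n_steps); ev_d.reserve(n_steps); }

  for (long long step = 0; step < (long long)n_steps; ++step) {
    if ((step & 0xFFFF) == 0 || a0 < 1e-9) {  // full refresh: drift control,
      a0 = 0.0;                               // and exact absorbing detection
      for (int d = 0; d < D; ++d) a0 += w[d];
    }
    if (a0 <= 0.0) { absorbed = true; break; }

    double dt = R::exp_rand() / a0;
    if (t + dt > t_max) {
      if (step >= tail_start && tail_len > 0) {
        double hold = t_max - t;
        for (int i = 0; i < m; ++i) tail_sum[i] += n[i] * hold;
        tail_time += hold;
      }
      t = t_max;
      hit_tmax = true;
      break;
    }

    double u = unif_rand() * a0;
    int d = 0;
    double c = w[0];
    while (u > c && d < D - 1) { ++d; c += w[d]; }

    if (step >= tail_start && tail_len > 0) {
      for (int i = 0; i < m; ++i) tail_sum[i] += n[i] * dt;
      tail_time += dt;
    }

    t += dt;
    const std::vector<std::pair<int, int> > &cc = ch[d];
    for (size_t j = 0; j < cc.size(); ++j) {
      n[cc[j].first] += cc[j].second;
      if (n[cc[j].first] < 0)
        stop("internal error: negative molecule count after event");
    }
    // refresh propensities of directions whose educts changed
    for (size_t j = 0; j < cc.size(); ++j) {
      const std::vector<int> &dd = dep[cc[j].first];
      for (size_t q = 0; q < dd.size(); ++q) {
        int d2 = dd[q];
        if (stamp[d2] == step) continue;   // both educts changed this event
        stamp[d2] = step;
        double wd = kV[d2];
        const std::vector<std::pair<int, int> > &e = ed[d2];
        for (size_t jj = 0; jj < e.size(); ++jj)
          wd *= ffact(n[e[jj].first], e[jj].second);
        a0 += wd - w[d2];
        w[d2] = wd;
      }
    }
    ++n_done;

    if (record_events) { ev_t.push_back(t); ev_d.push_back(d + 1); }
    if (record_stride > 0 && (n_done % record_stride) == 0) {
      snap_t.push_back(t);
      for (int i = 0; i < m; ++i) snap_n.push_back(n[i]);
    }
  }

  NumericVector final_counts(m);
  for (int i = 0; i < m; ++i) final_counts[i] = n[i];

  List out = List::create(
    _["counts"] = final_counts,
    _["time"] = t,
    _["n_events"] = (double)n_done,
    _["absorbed"] = absorbed,
    _["hit_tmax"] = hit_tmax);

  if (tail_len > 0 && tail_time > 0.0) {
    NumericVector tm(m);
    for (int i = 0; i < m; ++i) tm[i] = tail_sum[i] / tail_time;
    out["tail_mean"] = tm;
  }
  if (record_stride > 0) {
    int ns = (int)snap_t.size();
    NumericMatrix sm(ns, m);
    for (int r = 0; r < ns; ++r)
      for (int i = 0; i < m; ++i) sm(r, i) = snap_n[(size_t)r * m + i];
    out["snapshot_times"] = NumericVector(snap_t.begin(), snap_t.end());
    out["snapshots"] = sm;
  }
  if (record_events) {
    out["event_times"] = NumericVector(ev_t.begin(), ev_t.end());
    out["event_dirs"] = IntegerVector(ev_d.begin(), ev_d.end());
  }
  return out;
}
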