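#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Exact stochastic simulation of a cluster of n independent heads, each
// cycling 1 (unbound, ATP) -> 2 (bound, ADP) -> 3 (bound, rigor) -> 1.
// Transitions are irreversible; the 3->1 rate is k31 = k31_per_atp * [ATP].
//
// Per-filament anchor x: with >= 1 bound head, x = (rearmost bound head
// position) + s/2; with no bound head x keeps its last value.  A binding
// head lands at Normal(x + s/2, sd = s/2) on a filament chosen uniformly.
//
// Strain (two filaments) accrues from anchor jumps at events at which the
// cluster is crosslinked immediately before the event or (with
// strain_establish, the default at the R level) immediately after it, so
// the establishing binding's anchor jump counts as sliding.
//
// Uses R's RNG so set.seed() upstream gives bit-reproducible trajectories.

// [[Rcpp::export]]
List gillespie_core(int n_heads, int n_filaments, double step_size,
                    double k12, double k23, double k31,
                    double t_max, bool record_events, bool strain_establish) {
  const double s = step_size;
  std::vector<int> state(n_heads, 1);   // 1, 2, 3
  std::vector<int> fil(n_heads, -1);    // filament index 0/1 while bound
  std::vector<double> pos(n_heads, 0.0);
  double x[2] = {0.0, 0.0};             // per-filament anchors
  int bound[2] = {0, 0};

  double t = 0.0;
  double disp[2] = {0.0, 0.0};          // accumulated anchor displacement
  double strain = 0.0;                  // relative sliding while crosslinked
  double t_crosslinked = 0.0, t_bound = 0.0;

  // run bookkeeping (maximal intervals with >= 1 bound head anywhere)
  bool in_run = false;
  double run_start_x = 0.0;
  std::vector<double> run_lengths;
  bool open_run = false;

  std::vector<double> ev_t, ev_pos;
  std::vector<int> ev_head, ev_trans, ev_fil;

  const double rate_of[4] = {0.0, k12, k23, k31};

  for (;;) {
    double rtot = 0.0;
    for (int h = 0; h < n_heads; ++h) rtot += rate_of[state[h]];
    bool crosslinked = (n_filaments == 2) && bound[0] > 0 && bound[1] > 0;
    bool any_bound = (bound[0] + bound[1]) > 0;
    if (rtot <= 0.0) {  // absorbing (e.g. all heads in rigor at [ATP] = 0)
      if (crosslinked) t_crosslinked += t_max - t;
      if (any_bound) t_bound += t_max - t;
      t = t_max;
      break;
    }
    double dt = exp_rand() / rtot;
    if (t + dt >= t_max) {  // interval truncated at t_max, no event
      if (crosslinked) t_crosslinked += t_max - t;
      if (any_bound) t_bound += t_max - t;
      t = t_max;
      break;
    }
    if (crosslinked) t_crosslinked += dt;
    if (any_bound) t_bound += dt;
    t += dt;

    // pick transitioning head proportionally to its state's rate
    double r = unif_rand() * rtot;
    int head = n_heads - 1;
    double acc = 0.0;
    for (int h = 0; h < n_heads; ++h) {
      acc += rate_of[state[h]];
      if (r <= acc) { head = h; break; }
    }

    double x_old[2] = {x[0], x[1]};
    int trans;
    int ev_f = NA_INTEGER;
    double ev_p = NA_REAL;

    if (state[head] == 1) {             // bind
      trans = 12;
      int f = 0;
      if (n_filaments == 2) f = (unif_rand() < 0.5) ? 0 : 1;
      double p = x[f] + s / 2.0 + norm_rand() * (s / 2.0);
      state[head] = 2;
      fil[head] = f;
      pos[head] = p;
      ++bound[f];
      ev_f = f + 1;
      ev_p = p;
    } else if (state[head] == 2) {      // ADP release, stays bound
      trans = 23;
      state[head] = 3;
      ev_f = fil[head] + 1;
    } else {                            // unbind on ATP uptake
      trans = 31;
      int f = fil[head];
      --bound[f];
      state[head] = 1;
      fil[head] = -1;
      ev_f = f + 1;
    }

    // re-evaluate anchors: rearmost bound head + s/2 on occupied filaments
    for (int f = 0; f < n_filaments; ++f) {
      if (bound[f] > 0) {
        double rear = R_PosInf;
        for (int h = 0; h < n_heads; ++h)
          if (state[h] != 1 && fil[h] == f && pos[h] < rear) rear = pos[h];
        x[f] = rear + s / 2.0;
      }
    }

    disp[0] += x[0] - x_old[0];
    if (n_filaments == 2) {
      disp[1] += x[1] - x_old[1];
      bool crosslinked_now = bound[0] > 0 && bound[1] > 0;
      if (crosslinked || (strain_establish && crosslinked_now))
        strain += (x[0] - x_old[0]) + (x[1] - x_old[1]);
    }

    bool any_bound_now = (bound[0] + bound[1]) > 0;
    if (!in_run && any_bound_now) {
      in_run = true;
      run_start_x = x[0] + ((n_filaments == 2) ? x[1] : 0.0);
    } else if (in_run && !any_bound_now) {
      in_run = false;
      double xe = x[0] + ((n_filaments == 2) ? x[1] : 0.0);
      run_lengths.push_back(xe - run_start_x);
    }

    if (record_events) {
      ev_t.push_back(t);
      ev_head.push_back(head + 1);
      ev_trans.push_back(trans);
      ev_fil.push_back(ev_f);
      ev_pos.push_back(ev_p);
    }
  }

  if (in_run) {  // run still open at t_max: count distance travelled so far
    open_run = true;
    double xe = x[0] + ((n_filaments == 2) ? x[1] : 0.0);
    run_lengths.push_back(xe - run_start_x);
  }

  List events = R_NilValue;
  if (record_events) {
    events = DataFrame::create(
      _["t"] = ev_t, _["head"] = ev_head, _["transition"] = ev_trans,
      _["filament"] = ev_fil, _["position"] = ev_pos);
  }
  IntegerVector final_state(n_heads);
  for (int h = 0; h < n_heads; ++h) final_state[h] = state[h];

  return List::create(
    _["t_final"] = t,
    _["displacement"] = NumericVector::create(disp[0], disp[1]),
    _["anchor_final"] = NumericVector::create(x[0], x[1]),
    _["strain"] = strain,
    _["time_crosslinked"] = t_crosslinked,
    _["time_bound"] = t_bound,
    _["run_lengths"] = wrap(run_lengths),
    _["open_run"] = open_run,
    _["final_state"] = final_state,
    _["events"] = events);
}
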