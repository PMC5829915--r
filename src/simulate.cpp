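#include <Rcpp.h>
using namespace Rcpp;

// Exact event-driven simulation of one half-filament engaging an actin
// filament. State = bound motor counts per species (A, B). Attachment rate
// per free motor k_att, detachment rate per bound motor k_det. Between
// events the filament advances at the unloaded speed of the slowest species
// with at least one bound motor; position is integrated analytically. When
// the bound count reaches zero a rescue window of length `rescue_tau` runs:
// an attachment within it continues the run (no movement during the pause),
// otherwise the run terminates (all_detached). Termination is `reached_end`
// when the position reaches `actin_length` and `timeout` at `max_time`;
// both are censored observations of the run length.
//
// Units: positions/lengths in micrometres, times in seconds, speeds in
// micrometres per second. Uses the R RNG (seed from R via set.seed).
//
// termination codes: 0 = all_detached, 1 = reached_end, 2 = timeout

// [[Rcpp::export]]
List cpp_simulate_run(int nA, int nB,
                      double kattA, double kdetA,
                      double kattB, double kdetB,
                      double vA, double vB,
                      double start_pos, double actin_length,
                      double max_time, double rescue_tau,
                      NumericVector frame_times,
                      bool record) {
  const int nF = frame_times.size();
  NumericVector fpos(nF, NA_REAL);
  int fi = 0;

  std::vector<double> ev_t, ev_x;
  std::vector<int> ev_bA, ev_bB;

  double t = 0.0, pos = start_pos;
  int bA = 0, bB = 0;
  double bound_time = 0.0;   // integral of bound count over time (motor-s)
  double pause_time = 0.0;   // time spent with zero bound motors
  long n_events = 0;
  int termination;

  const double attTotal0 = nA * kattA + nB * kattB;

  auto rec = [&](void) {
    if (record) {
      ev_t.push_back(t); ev_x.push_back(pos);
      ev_bA.push_back(bA); ev_bB.push_back(bB);
    }
  };

  auto fill_frames = [&](double t0, double t1, double x0, double v) {
    while (fi < nF && frame_times[fi] <= t1 + 1e-12) {
      double ft = frame_times[fi];
      if (ft >= -1e-12) fpos[fi] = x0 + v * std::max(0.0, ft - t0);
      ++fi;
    }
  };

  if (nA + nB == 0 || attTotal0 <= 0.0) {
    // no motor domains: run of length zero, immediate dissociation
    return List::create(_["run_length"] = 0.0, _["duration"] = 0.0,
                        _["termination"] = 0, _["censored"] = false,
                        _["final_pos"] = pos, _["start_pos"] = start_pos,
                        _["bound_time"] = 0.0, _["pause_time"] = 0.0,
                        _["n_events"] = 0L,
                        _["frame_pos"] = fpos,
                        _["events"] = R_NilValue);
  }

  // the run begins with the attachment that initiates it
  if (unif_rand() * attTotal0 < nA * kattA) bA = 1; else bB = 1;
  rec();

  if (pos >= actin_length) {
    fill_frames(0.0, 0.0, pos, 0.0);
    return List::create(_["run_length"] = 0.0, _["duration"] = 0.0,
                        _["termination"] = 1, _["censored"] = true,
                        _["final_pos"] = pos, _["start_pos"] = start_pos,
                        _["bound_time"] = 0.0, _["pause_time"] = 0.0,
                        _["n_events"] = 0L, _["frame_pos"] = fpos,
                        _["events"] = R_NilValue);
  }

  for (;;) {
    if (bA + bB == 0) {
      // rescue window: no movement, wait for a reattachment
      double dt_att = exp_rand() / attTotal0;
      bool rescued = R_finite(rescue_tau) ? (dt_att <= rescue_tau) : true;
      double dwell = rescued ? dt_att : rescue_tau;
      if (t + dwell >= max_time) {         // observation window ends first
        double dt = max_time - t;
        pause_time += dt;
        fill_frames(t, max_time, pos, 0.0);
        t = max_time;
        termination = 2;
        break;
      }
      fill_frames(t, t + dwell, pos, 0.0);
      pause_time += dwell;
      t += dwell;
      if (!rescued) { termination = 0; break; }
      if (unif_rand() * attTotal0 < nA * kattA) bA = 1; else bB = 1;
      ++n_events;
      rec();
      continue;
    }

    double rAatt = (nA - bA) * kattA, rAdet = bA * kdetA;
    double rBatt = (nB - bB) * kattB, rBdet = bB * kdetB;
    double total = rAatt + rAdet + rBatt + rBdet;
    double v = R_PosInf;                  // slowest bound species moves it
    if (bA > 0) v = std::min(v, vA);
    if (bB > 0) v = std::min(v, vB);
    if (!R_finite(v)) v = 0.0;

    double dt = exp_rand() / total;
    double t_hit = (v > 0.0) ? t + (actin_length - pos) / v : R_PosInf;

    if (t_hit <= t + dt && t_hit <= max_time) {   // reaches the actin end
      fill_frames(t, t_hit, pos, v);
      bound_time += (bA + bB) * (t_hit - t);
      pos = actin_length;
      t = t_hit;
      termination = 1;
      break;
    }
    if (t + dt >= max_time) {                      // observation timeout
      fill_frames(t, max_time, pos, v);
      bound_time += (bA + bB) * (max_time - t);
      pos += v * (max_time - t);
      t = max_time;
      termination = 2;
      break;
    }

    fill_frames(t, t + dt, pos, v);
    bound_time += (bA + bB) * dt;
    pos += v * dt;
    t += dt;

    double u = unif_rand() * total;
    if (u < rAatt)                      ++bA;
    else if (u < rAatt + rAdet)         --bA;
    else if (u < rAatt + rAdet + rBatt) ++bB;
    else                                --bB;
    ++n_events;
    rec();
  }

  fill_frames(t, t, pos, 0.0);   // frames exactly at the termination time
  rec();

  List events = R_NilValue;
  if (record) {
    events = List::create(_["time"] = wrap(ev_t), _["position"] = wrap(ev_x),
                          _["bound_A"] = wrap(ev_bA), _["bound_B"] = wrap(ev_bB));
  }
  return List::create(_["run_length"] = pos - start_pos, _["duration"] = t,
                      _["termination"] = termination,
                      _["censored"] = termination != 0,
                      _["final_pos"] = pos, _["start_pos"] = start_pos,
                      _["bound_time"] = bound_time,
                      _["pause_time"] = pause_time,
                      _["n_events"] = (double) n_events,
                      _["frame_pos"] = fpos,
                      _["events"] = events);
}
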