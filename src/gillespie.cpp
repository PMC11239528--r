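#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Continuous-time Gillespie simulation of a joint photophysical model.
//
// Channels are (from, to, rate, photon) rows; photon codes:
//   0 none, 1 donor radiative/non-radiative split, 2 acceptor split.
// A photon-coded channel emits with probability p_em (= k_em/(k_em+k_nr))
// of its dye at transition time; an emitted photon is detected with
// probability eta of its channel.  Uses R's RNG so results are
// reproducible under set.seed().
//
// [[Rcpp::export]]
List gillespie_run_cpp(IntegerVector ch_from, IntegerVector ch_to,
                       NumericVector ch_rate, IntegerVector ch_photon,
                       int n_states, double duration,
                       double p_em_d, double p_em_a,
                       double eta_d, double eta_a,
                       bool record_dwells, bool detected_only) {
  const int n_ch = ch_from.size();

  // per-state channel index lists and total exit rates
  std::vector< std::vector<int> > idx(n_states);
  std::vector<double> exit_rate(n_states, 0.0);
  for (int c = 0; c < n_ch; ++c) {
    idx[ch_from[c] - 1].push_back(c);
    exit_rate[ch_from[c] - 1] += ch_rate[c];
  }

  std::vector<double> ph_time;
  std::vector<int> ph_chan;          // 1 donor, 2 acceptor
  std::vector<int> ph_det;
  std::vector<int> dw_state;
  std::vector<double> dw_enter, dw_exit;

  long long n_rad_d = 0, n_rad_a = 0;   // radiative transitions = emitted
  long long n_det_d = 0, n_det_a = 0;
  long long n_events = 0;

  RNGScope scope;
  double t = 0.0;
  int s = 0;  // state index (0-based), start in ground state
  double t_enter = 0.0;

  while (true) {
    const double R = exit_rate[s];
    if (R <= 0.0)
      stop("state '%d' has zero exit rate: simulation cannot proceed", s + 1);
    const double dt = -std::log(unif_rand()) / R;
    double t_next = t + dt;
    if (t_next >= duration) {
      if (record_dwells) {
        dw_state.push_back(s + 1);
        dw_enter.push_back(t_enter);
        dw_exit.push_back(duration);
      }
      break;
    }
    // choose channel
    double u = unif_rand() * R;
    const std::vector<int> &cand = idx[s];
    int chosen = cand.back();
    double acc = 0.0;
    for (size_t k = 0; k < cand.size(); ++k) {
      acc += ch_rate[cand[k]];
      if (u <= acc) { chosen = cand[k]; break; }
    }
    const int ph = ch_photon[chosen];
    if (ph != 0) {
      const double p_em = (ph == 1) ? p_em_d : p_em_a;
      if (unif_rand() < p_em) {
        if (ph == 1) ++n_rad_d; else ++n_rad_a;
        const double eta = (ph == 1) ? eta_d : eta_a;
        const bool det = unif_rand() < eta;
        if (det) { if (ph == 1) ++n_det_d; else ++n_det_a; }
        if (det || !detected_only) {
          ph_time.push_back(t_next);
          ph_chan.push_back(ph);
          ph_det.push_back(det ? 1 : 0);
        }
      }
    }
    if (record_dwells) {
      dw_state.push_back(s + 1);
      dw_enter.push_back(t_enter);
      dw_exit.push_back(t_next);
    }
    s = ch_to[chosen] - 1;
    t = t_next;
    t_enter = t_next;
    ++n_events;
    if ((n_events & 0xFFFFF) == 0) checkUserInterrupt();
  }

  return List::create(
    _["time"] = NumericVector(ph_time.begin(), ph_time.end()),
    _["channel"] = IntegerVector(ph_chan.begin(), ph_chan.end()),
    _["detected"] = IntegerVector(ph_det.begin(), ph_det.end()),
    _["dwell_state"] = IntegerVector(dw_state.begin(), dw_state.end()),
    _["dwell_enter"] = NumericVector(dw_enter.begin(), dw_enter.end()),
    _["dwell_exit"] = NumericVector(dw_exit.begin(), dw_exit.end()),
    _["n_emitted_donor"] = (double)n_rad_d,
    _["n_emitted_acceptor"] = (double)n_rad_a,
    _["n_detected_donor"] = (double)n_det_d,
    _["n_detected_acceptor"] = (double)n_det_a,
    _["n_events"] = (double)n_events);
}
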