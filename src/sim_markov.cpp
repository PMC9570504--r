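#include <Rcpp.h>
using namespace Rcpp;

// Discrete-time three-state gating chain stepped at the sampling interval.
// States: 0 = main open, 1 = residual, 2 = fully closed.
// Per-sample transition probabilities are 1 - exp(-rate * dt), precomputed in R.
// A closing event lands in the fully closed state with probability p_to_full,
// otherwise in the residual state; both gated states reopen with the same rate,
// so the open-state occupancy keeps the two-state Boltzmann stationary law.
// Uses R's RNG so results are reproducible under set.seed().

// [[Rcpp::export]]
List sim_markov_cpp(IntegerVector init, int n_samples,
                    double p_leave_open, double p_to_full, double p_return,
                    bool keep_states) {
  int nc = init.size();
  std::vector<int> state(init.begin(), init.end());
  IntegerVector n_open(n_samples), n_res(n_samples);
  IntegerMatrix states;
  if (keep_states) states = IntegerMatrix(n_samples, nc);

  for (int t = 0; t < n_samples; ++t) {
    int no = 0, nr = 0;
    for (int c = 0; c < nc; ++c) {
      double u = unif_rand();
      if (state[c] == 0) {
        if (u < p_leave_open)
          state[c] = (unif_rand() < p_to_full) ? 2 : 1;
      } else {
        if (u < p_return) state[c] = 0;
      }
      if (state[c] == 0) ++no;
      else if (state[c] == 1) ++nr;
      if (keep_states) states(t, c) = state[c];
    }
    n_open[t] = no;
    n_res[t] = nr;
  }

  List out = List::create(_["n_open"] = n_open, _["n_res"] = n_res,
                          _["final"] = IntegerVector(state.begin(), state.end()));
  if (keep_states) out["states"] = states;
  return out;
}
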