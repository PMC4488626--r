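#include <Rcpp.h>
using namespace Rcpp;

// Leaky integrate-and-fire population evaluator.
//
// Neuron order: 0 cue_left, 1 cue_neutral, 2 cue_right, 3 target_left,
// 4 target_right, then outputs: 5 (SRT) or 5 = output_left, 6 = output_right
// (CRT). A genome is N biases followed by the N*(N-1) directed weights in
// row-major order over ordered pairs (i, j), i != j (weight from i to j).
//
// Dynamics per time unit: I_j = bias_j + external current (stim_current on a
// stimulated input neuron) + sum of weights from neurons that spiked on the
// previous step + Gaussian noise; V_j <- v_rest + (V_j - v_rest) * exp(-1/tau)
// + I_j; a neuron reaching v_threshold spikes and is reset to v_reset before
// the next step. Updates are synchronous.
//
// Timeline per trial: steps 1..pre_cue silent; cue current on from step
// pre_cue+1 onward (it stays on after target onset); target current on from
// step t_first = pre_cue + cue_duration + 1, the target-onset step. The trial
// ends at the first output spike or after post_target_limit target-stimulated
// steps. rt = spike step - t_first: the earliest response mediated by a
// target-neuron spike (one synaptic step after onset) has rt = 1, the
// discrete-time floor; rt <= 0 means the output fired at or before onset,
// i.e. not driven by the target, and the trial is anticipated.
//
// RNG: uses R's generator (seed with set.seed()). Draw order: for each
// individual, for each trial: cue duration (if not supplied), then one
// Gaussian per neuron per time unit when noise_sigma > 0, then a tie-break
// uniform if both CRT outputs fire on the same step.
//
// Outcome codes: 0 correct, 1 anticipated, 2 incorrect, 3 slow.

// [[Rcpp::export]]
List eval_lif_population_cpp(NumericMatrix genomes, bool crt,
                             IntegerVector cue_neuron,
                             IntegerVector target_neuron,
                             double noise_sigma,
                             int pre_cue, int cue_min, int cue_max,
                             double stim_current, int post_target_limit,
                             double v_rest, double v_reset,
                             double v_threshold, double tau,
                             IntegerMatrix cue_durations) {
  const int n_ind = genomes.nrow();
  const int n_trials = cue_neuron.size();
  const int N = crt ? 7 : 6;
  const int expected_len = N + N * (N - 1);
  if (genomes.ncol() != expected_len)
    stop("genome length %d does not match architecture (expected %d)",
         genomes.ncol(), expected_len);
  if (target_neuron.size() != n_trials)
    stop("cue_neuron and target_neuron must have equal length");
  const bool fixed_cd = cue_durations.nrow() > 0;
  if (fixed_cd &&
      (cue_durations.nrow() != n_ind || cue_durations.ncol() != n_trials))
    stop("cue_durations must be n_individuals x n_trials");

  const double decay = std::exp(-1.0 / tau);
  const int out_a = 5;            // SRT output / CRT left output
  const int out_b = crt ? 6 : -1; // CRT right output

  IntegerMatrix rt(n_ind, n_trials);
  IntegerMatrix outcome(n_ind, n_trials);
  NumericVector fitness(n_ind);

  std::vector<double> b(N), W(N * N), V(N);
  std::vector<int> spike(N), prev(N);

  for (int ind = 0; ind < n_ind; ++ind) {
    for (int j = 0; j < N; ++j) b[j] = genomes(ind, j);
    int k = N;
    for (int i = 0; i < N; ++i)
      for (int j = 0; j < N; ++j) {
        if (i == j) { W[i * N + j] = 0.0; continue; }
        W[i * N + j] = genomes(ind, k++);
      }

    double total_fit = 0.0;
    for (int tr = 0; tr < n_trials; ++tr) {
      int cd;
      if (fixed_cd) {
        cd = cue_durations(ind, tr);
      } else {
        cd = cue_min + (int)(unif_rand() * (cue_max - cue_min + 1));
        if (cd > cue_max) cd = cue_max;
      }
      const int t_first = pre_cue + cd + 1; // target-onset step
      const int t_end = t_first + post_target_limit - 1;
      const int cn = cue_neuron[tr], tn = target_neuron[tr];

      for (int j = 0; j < N; ++j) { V[j] = v_rest; prev[j] = 0; }
      int resp_t = NA_INTEGER, resp_out = -1;

      for (int t = 1; t <= t_end; ++t) {
        for (int j = 0; j < N; ++j) {
          double I = b[j];
          if (t > pre_cue && j == cn) I += stim_current;
          if (t >= t_first && j == tn) I += stim_current;
          for (int i = 0; i < N; ++i)
            if (prev[i]) I += W[i * N + j];
          if (noise_sigma > 0.0) I += noise_sigma * norm_rand();
          double Vn = v_rest + (V[j] - v_rest) * decay + I;
          if (Vn >= v_threshold) { spike[j] = 1; Vn = v_reset; }
          else spike[j] = 0;
          V[j] = Vn;
        }
        bool sa = spike[out_a] != 0;
        bool sb = crt && spike[out_b] != 0;
        if (sa || sb) {
          resp_t = t;
          if (sa && sb) resp_out = (unif_rand() < 0.5) ? out_a : out_b;
          else resp_out = sa ? out_a : out_b;
          break;
        }
        for (int j = 0; j < N; ++j) prev[j] = spike[j];
      }

      int oc;
      int this_rt = NA_INTEGER;
      if (resp_t == NA_INTEGER) {
        oc = 3; // slow
      } else {
        this_rt = resp_t - t_first;
        if (this_rt <= 0) {
          oc = 1; // anticipated: fired at or before the onset step
        } else if (!crt) {
          oc = 0;
        } else {
          // target_left (3) maps to output_left (5)
          bool match = (tn == 3 && resp_out == 5) || (tn == 4 && resp_out == 6);
          oc = match ? 0 : 2;
        }
      }
      rt(ind, tr) = this_rt;
      outcome(ind, tr) = oc;
      if (oc == 0) total_fit += 1000.0 * std::exp(-0.01 * this_rt);
    }
    fitness[ind] = total_fit;
  }

  return List::create(_["fitness"] = fitness, _["rt"] = rt,
                      _["outcome"] = outcome);
}
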