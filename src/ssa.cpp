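#include <Rcpp.h>
using namespace Rcpp;

// Promoter states of the initiation model. One promoter copy per cell.
enum PromState { OFF_REPRESSED = 0, ON_FREE = 1, CLOSED_COMPLEX = 2, LOCKED = 3 };

// Exact stochastic simulation (direct method) of the promoter reaction
// system. Delayed RNA-appearance events never alter propensities, so it is
// sufficient to record commitment (k2 firing) times and shift them by the
// observation delay on the R side.
//
// Reactions:
//   ON_free        --k1*rnap_level-->  CLOSED_complex
//   CLOSED_complex --k_minus1------->  ON_free
//   CLOSED_complex --k2------------->  ON_free + RNA(t + delay)
//   ON_free        --k_cc----------->  LOCKED            (lock_mode first_order)
//   after k2 fires, LOCKED with prob p_lock              (lock_mode per_initiation)
//   LOCKED         --k_unlock------->  ON_free
//   ON_free        --k_rep_bind----->  OFF_repressed
//   OFF_repressed  --k_rep_unbind--->  ON_free
//
// k_unlock = +Inf disables the lock channel entirely (LOCKED unreachable).
// Uses R's RNG stream: seeding via set.seed() on the R side makes runs
// bit-reproducible.
//
// If stop_after_n_commits > 0 the walk stops after that many commitment
// events regardless of t_end (used for direct inter-event interval
// sampling); otherwise it runs until t_end.
// [[Rcpp::export]]
NumericVector ssa_commit_times(double k1, double k_minus1, double k2,
                               double k_cc, double k_unlock,
                               double k_rep_unbind, double k_rep_bind,
                               double rnap_level,
                               bool lock_per_initiation, double p_lock,
                               double t_end, int stop_after_n_commits) {
  const bool lock_enabled = R_finite(k_unlock);
  const double a_bind = k1 * rnap_level;
  std::vector<double> commits;
  if (stop_after_n_commits > 0) commits.reserve(stop_after_n_commits);

  int state = ON_FREE;
  double t = 0.0;
  // Hard cap so pathological rate combinations cannot spin forever.
  const long max_steps = 100000000L;
  long steps = 0;

  while (steps++ < max_steps) {
    double total;
    switch (state) {
      case ON_FREE:
        total = a_bind + k_rep_bind + (lock_enabled && !lock_per_initiation ? k_cc : 0.0);
        break;
      case CLOSED_COMPLEX:
        total = k_minus1 + k2;
        break;
      case LOCKED:
        total = k_unlock;
        break;
      default: // OFF_REPRESSED
        total = k_rep_unbind;
    }
    if (total <= 0.0) break; // absorbed (e.g. k_unlock = 0, or no channels)

    t += R::exp_rand() / total;
    if (stop_after_n_commits <= 0 && t > t_end) break;

    const double u = unif_rand() * total;
    if (state == ON_FREE) {
      if (u < a_bind) {
        state = CLOSED_COMPLEX;
      } else if (u < a_bind + k_rep_bind) {
        state = OFF_REPRESSED;
      } else {
        state = LOCKED;
      }
    } else if (state == CLOSED_COMPLEX) {
      if (u < k2) {
        commits.push_back(t); // RNA appears at t + rna_delay
        state = ON_FREE;
        if (lock_enabled && lock_per_initiation && unif_rand() < p_lock)
          state = LOCKED;
        if (stop_after_n_commits > 0 &&
            (int)commits.size() >= stop_after_n_commits)
          break;
      } else {
        state = ON_FREE;
      }
    } else if (state == LOCKED) {
      state = ON_FREE;
    } else { // OFF_REPRESSED
      state = ON_FREE;
    }
  }
  return wrap(commits);
}
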