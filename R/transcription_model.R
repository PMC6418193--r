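#' Kinetic parameters of the transcription initiation model
#'
#' Bundles all rate constants and delays of the initiation model with
#' promoter locking. The model describes a single promoter copy per cell
#' cycling between a repressor-bound state, a free state, a reversible
#' closed RNAP-promoter complex, and a supercoiling-induced "locked" state;
#' commitment to open complex formation (the `k2` firing) is irreversible
#' and produces an observable RNA after a fixed delay.
#'
#' Rates are per minute; RNAP enters as a fixed relative concentration
#' (pseudo-first-order binding at rate `k1 * rnap_level`), not as a
#' depletable species.
#'
#' @param k1 RNAP binding rate constant, per relative RNAP unit per minute.
#' @param k_minus1 Closed-complex dissociation rate, per minute.
#' @param k2 Commitment (open complex completion) rate, per minute.
#' @param k_cc Promoter locking rate from the free state (supercoiling
#'   buildup), per minute. Used when `lock_mode = "first_order"`.
#' @param k_unlock Promoter unlocking rate, per minute. `Inf` is accepted
#'   and disables the lock channel entirely.
#' @param k_rep_unbind Repressor unbinding rate (often written k_ON), per
#'   minute.
#' @param k_rep_bind Repressor binding rate, per minute; 0 under full
#'   induction.
#' @param rnap_level Relative RNAP concentration (dimensionless; 1 is the
#'   control "1X" condition).
#' @param rna_delay Delay from commitment to observable RNA appearance,
#'   minutes. Affects only the observation offset, never the mean
#'   inter-transcription interval.
#' @param lock_mode Either `"first_order"` (locking races RNAP binding on
#'   the free promoter at rate `k_cc`) or `"per_initiation"` (the promoter
#'   enters the locked state with probability `p_lock` immediately after
#'   each commitment, emulating transcription-generated supercoiling).
#' @param p_lock Locking probability per initiation, in `[0, 1]`. Only used
#'   with `lock_mode = "per_initiation"`.
#'
#' @return An object of class `transcription_params`.
#' @examples
#' p <- transcription_params(k1 = 1, k2 = 1)
#' mean_interval_closed_form(p)
#' @export
transcription_params <- function(k1 = 4, k_minus1 = 0.035, k2 = 0.035,
                                 k_cc = 4.7, k_unlock = 1,
                                 k_rep_unbind = 1, k_rep_bind = 0,
                                 rnap_level = 1, rna_delay = 1,
                                 lock_mode = c("first_order", "per_initiation"),
                                 p_lock = 0) {
  lock_mode <- match.arg(lock_mode)
  p <- structure(
    list(k1 = k1, k_minus1 = k_minus1, k2 = k2, k_cc = k_cc,
         k_unlock = k_unlock, k_rep_unbind = k_rep_unbind,
         k_rep_bind = k_rep_bind, rnap_level = rnap_level,
         rna_delay = rna_delay, lock_mode = lock_mode, p_lock = p_lock),
    class = "transcription_params")
  validate_transcription_params(p)
  p
}

#' Validate a transcription_params object
#'
#' Checks all model invariants: non-negative finite rates (except
#' `k_unlock`, which may be `Inf`), positive RNAP level, non-negative
#' delay, and `p_lock` in `[0, 1]`.
#'
#' @param p A `transcription_params` object.
#' @return `p`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_transcription_params <- function(p) {
  stopifnot(inherits(p, "transcription_params"))
  finite_rates <- c("k1", "k_minus1", "k2", "k_cc", "k_rep_unbind",
                    "k_rep_bind")
  for (nm in finite_rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || !is.finite(v))
      stop(sprintf("parameter '%s' must be a finite non-negative rate, got %s",
                   nm, format(v)), call. = FALSE)
  }
  v <- p$k_unlock
  if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
    stop("parameter 'k_unlock' must be a non-negative rate (Inf allowed)",
         call. = FALSE)
  if (!is.numeric(p$rnap_level) || p$rnap_level <= 0 || !is.finite(p$rnap_level))
    stop("parameter 'rnap_level' must be > 0", call. = FALSE)
  if (!is.numeric(p$rna_delay) || p$rna_delay < 0 || !is.finite(p$rna_delay))
    stop("parameter 'rna_delay' must be a finite non-negative delay",
         call. = FALSE)
  if (!p$lock_mode %in% c("first_order", "per_initiation"))
    stop("lock_mode must be 'first_order' or 'per_initiation'", call. = FALSE)
  if (!is.numeric(p$p_lock) || is.na(p$p_lock) || p$p_lock < 0 || p$p_lock > 1)
    stop("parameter 'p_lock' must be in [0, 1]", call. = FALSE)
  invisible(p)
}

#' @export
print.transcription_params <- function(x, ...) {
  cat("Transcription initiation model parameters (per minute):\n")
  cat(sprintf("  k1 = %g, k_minus1 = %g, k2 = %g\n", x$k1, x$k_minus1, x$k2))
  cat(sprintf("  lock: mode = %s, k_cc = %g, k_unlock = %g, p_lock = %g\n",
              x$lock_mode, x$k_cc, x$k_unlock, x$p_lock))
  cat(sprintf("  repressor: k_rep_unbind = %g, k_rep_bind = %g\n",
              x$k_rep_unbind, x$k_rep_bind))
  cat(sprintf("  rnap_level = %g, rna_delay = %g min\n",
              x$rnap_level, x$rna_delay))
  invisible(x)
}

# Low-level call into the compiled direct-method walker. Returns commitment
# times (before adding rna_delay). Seeding is done by the caller.
ssa_run <- function(p, t_end, stop_after_n_commits = 0L) {
  ssa_commit_times(p$k1, p$k_minus1, p$k2, p$k_cc, p$k_unlock,
                   p$k_rep_unbind, p$k_rep_bind, p$rnap_level,
                   p$lock_mode == "per_initiation", p$p_lock,
                   t_end, as.integer(stop_after_n_commits))
}

#' Simulate a single-cell RNA trajectory
#'
#' Runs an exact stochastic simulation (direct method with delayed RNA
#' appearance events) of the initiation model for one cell, starting with a
#' free promoter, and reports cumulative RNA counts on a sampling grid.
#' Tagged RNAs are effectively non-degraded, so counts are non-decreasing.
#'
#' @param params A [transcription_params()] object.
#' @param t_end Simulation end time, minutes (> 0).
#' @param sample_times Ascending grid of sampling times within `[0, t_end]`.
#' @param seed Integer seed; the trajectory is bit-reproducible given the
#'   seed and parameters.
#' @param initial_rna Non-negative integer count of RNAs present at t = 0.
#' @return An object of class `cell_trajectory` with fields `sample_times`,
#'   `rna_counts`, `seed`, `initial_rna`, and an attribute `rna_times`
#'   holding the appearance times of new RNAs (commitment time + delay).
#' @examples
#' tr <- simulate_cell(transcription_params(), t_end = 75,
#'                     sample_times = seq(0, 75, 15), seed = 1)
#' tr$rna_counts
#' @export
simulate_cell <- function(params, t_end, sample_times = seq(0, t_end, 15),
                          seed = 1L, initial_rna = 0L) {
  validate_transcription_params(params)
  if (!is.numeric(t_end) || t_end <= 0)
    stop("t_end must be > 0", call. = FALSE)
  if (is.unsorted(sample_times, strictly = TRUE))
    stop("sample_times must be a strictly ascending grid", call. = FALSE)
  if (min(sample_times) < 0 || max(sample_times) > t_end)
    stop("sample_times must lie within [0, t_end]", call. = FALSE)
  if (initial_rna < 0 || initial_rna != round(initial_rna))
    stop("initial_rna must be a non-negative integer", call. = FALSE)

  set.seed(as.integer(seed))
  commits <- ssa_run(params, t_end)
  rna_times <- commits + params$rna_delay
  counts <- initial_rna +
    vapply(sample_times, function(ts) sum(rna_times <= ts), numeric(1))
  structure(
    list(sample_times = as.numeric(sample_times),
         rna_counts = as.integer(counts),
         seed = as.integer(seed),
         initial_rna = as.integer(initial_rna)),
    rna_times = rna_times,
    class = "cell_trajectory")
}

#' Sample inter-transcription intervals directly
#'
#' Runs the model from a free promoter until `n_intervals` commitment
#' events have occurred and returns the waiting times between consecutive
#' commitments (the first interval is the time from t = 0 to the first
#' commitment; since the promoter returns to the free state after each
#' commitment, intervals are independent and identically distributed).
#' This gives an unbiased empirical estimate of the mean interval,
#' avoiding the censoring bias of fixed-horizon runs, and serves as the
#' simulation side of the closed-form oracle check.
#'
#' @param params A [transcription_params()] object with `k_rep_bind = 0`
#'   and a reachable commitment channel.
#' @param n_intervals Number of intervals to sample (>= 1).
#' @param seed Integer seed.
#' @return Numeric vector of `n_intervals` waiting times, minutes.
#' @export
simulate_intervals <- function(params, n_intervals, seed = 1L) {
  validate_transcription_params(params)
  if (n_intervals < 1) stop("n_intervals must be >= 1", call. = FALSE)
  if (params$k1 <= 0 || params$k2 <= 0)
    stop("k1 and k2 must be > 0 for transcription to occur", call. = FALSE)
  if (params$k_cc > 0 && params$k_unlock == 0 &&
      params$lock_mode == "first_order")
    stop("lock state is absorbing (k_unlock = 0): intervals undefined",
         call. = FALSE)
  set.seed(as.integer(seed))
  commits <- ssa_run(params, Inf, stop_after_n_commits = n_intervals)
  diff(c(0, commits))
}

#' Closed-form mean inter-transcription interval
#'
#' First-step analysis of the promoter Markov chain under full induction
#' gives the mean time between consecutive commitment events:
#' \deqn{\Delta t = (1 + k_{-1}/k_2)\,\frac{1}{k_1 R}\,(1 + k_{cc}/k_{unlock})
#'   + 1/k_2}
#' where \eqn{R} is the relative RNAP concentration. For
#' `k_unlock = Inf` the locking factor is 1. In `per_initiation` mode the
#' lock dwell is paid once per initiation instead:
#' \eqn{\Delta t = (1 + k_{-1}/k_2)/(k_1 R) + 1/k_2 + p_{lock}/k_{unlock}}.
#'
#' This is the analytic oracle for the stochastic engine and carries the
#' same structure as the Lineweaver-Burk plot: the term
#' \eqn{1/k_2} is RNAP-independent (time after commitment), the rest scales
#' with \eqn{1/R} (time prior to commitment).
#'
#' @param params A [transcription_params()] object with `k_rep_bind = 0`.
#' @return Mean interval, minutes.
#' @examples
#' mean_interval_closed_form(
#'   transcription_params(k1 = 1, k_minus1 = 0, k2 = 1, k_cc = 0))
#' @export
mean_interval_closed_form <- function(params) {
  validate_transcription_params(params)
  if (params$k_rep_bind > 0)
    stop("no closed form implemented for k_rep_bind > 0 (partial induction)",
         call. = FALSE)
  if (params$k1 <= 0 || params$k2 <= 0)
    stop("closed form requires k1 > 0 and k2 > 0", call. = FALSE)
  pre <- (1 + params$k_minus1 / params$k2) / (params$k1 * params$rnap_level)
  if (params$lock_mode == "first_order") {
    lock_factor <- if (is.infinite(params$k_unlock)) 1
                   else 1 + params$k_cc / params$k_unlock
    if (params$k_cc > 0 && params$k_unlock == 0)
      stop("lock state is absorbing (k_unlock = 0): mean interval infinite",
           call. = FALSE)
    pre * lock_factor + 1 / params$k2
  } else {
    lock_dwell <- if (is.infinite(params$k_unlock)) 0
                  else if (params$p_lock == 0) 0
                  else if (params$k_unlock == 0)
                    stop("lock state is absorbing (k_unlock = 0)", call. = FALSE)
                  else params$p_lock / params$k_unlock
    pre + 1 / params$k2 + lock_dwell
  }
}

#' Theoretical pre/post-commitment fractions of the initiation interval
#'
#' Splits the closed-form mean interval into the RNAP-independent portion
#' after commitment, \eqn{t_{after} = 1/k_2}, and the remainder prior to
#' commitment, and returns both as fractions of the whole (they sum to 1).
#' These are the quantities a Lineweaver-Burk decomposition of measured
#' production rates estimates empirically.
#'
#' @inheritParams mean_interval_closed_form
#' @return Named numeric vector `c(t_prior_frac, t_after_frac)`.
#' @examples
#' theoretical_fractions(
#'   transcription_params(k1 = 1, k_minus1 = 0, k2 = 1, k_cc = 0))
#' @export
theoretical_fractions <- function(params) {
  dt <- mean_interval_closed_form(params)
  t_after <- 1 / params$k2
  c(t_prior_frac = (dt - t_after) / dt, t_after_frac = t_after / dt)
}

#' @export
print.cell_trajectory <- function(x, ...) {
  cat(sprintf("Single-cell RNA trajectory (seed %d, initial RNA %d):\n",
              x$seed, x$initial_rna))
  print(stats::setNames(x$rna_counts, paste0(x$sample_times, "min")))
  invisible(x)
}
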