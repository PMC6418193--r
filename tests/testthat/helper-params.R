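# Parameter sets used across tests. All are under full induction
# (k_rep_bind = 0) unless stated otherwise.

# simple no-lock chains
params_two_step <- function()
  transcription_params(k1 = 1, k_minus1 = 0, k2 = 1, k_cc = 0, k_unlock = Inf)

params_symmetric_lock <- function()
  transcription_params(k1 = 1, k_minus1 = 1, k2 = 1, k_cc = 1, k_unlock = 1)

# sets spanning t_prior_frac ~ {0.05, 0.25, 0.5} plus one constructed to
# give (0.27, 0.73), for the decomposition round trips
decomposition_param_sets <- function() {
  list(
    frac05 = transcription_params(k1 = 3.8, k_minus1 = 0, k2 = 0.2,
                                  k_cc = 0, k_unlock = Inf),
    frac25 = transcription_params(k1 = 2, k_minus1 = 1 / 3, k2 = 1 / 3,
                                  k_cc = 0, k_unlock = Inf),
    frac50 = transcription_params(k1 = 1, k_minus1 = 0, k2 = 0.5,
                                  k_cc = 1, k_unlock = 1),
    frac27 = transcription_params(k1 = 3 / 1.08, k_minus1 = 1 / 2.92,
                                  k2 = 1 / 2.92, k_cc = 0.5, k_unlock = 1))
}

# build a population_run by hand from a count matrix (cells x times),
# bypassing the simulator, for arithmetic tests of the normalization
fake_population_run <- function(counts, sample_times) {
  trajectories <- lapply(seq_len(nrow(counts)), function(i) {
    structure(list(sample_times = sample_times,
                   rna_counts = as.integer(counts[i, ]),
                   seed = i, initial_rna = counts[i, 1]),
              class = "cell_trajectory")
  })
  structure(list(params = transcription_params(),
                 trajectories = trajectories, sample_times = sample_times,
                 mean_rna = colMeans(counts), seed = 0L),
            class = "population_run")
}
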