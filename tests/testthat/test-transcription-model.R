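test_that("parameter validation rejects invalid inputs", {
  expect_error(transcription_params(k1 = -1), "k1")
  expect_error(transcription_params(rnap_level = 0), "rnap_level")
  expect_error(transcription_params(rna_delay = -0.1), "rna_delay")
  expect_error(transcription_params(p_lock = 1.5), "p_lock")
  expect_error(transcription_params(k_cc = Inf), "k_cc")
  # k_unlock = Inf is the one rate allowed to be infinite
  expect_s3_class(transcription_params(k_unlock = Inf), "transcription_params")

  p <- transcription_params()
  expect_error(simulate_cell(p, t_end = 0, sample_times = 0), "t_end")
  expect_error(simulate_cell(p, t_end = 10, sample_times = c(5, 1)),
               "ascending")
  expect_error(simulate_cell(p, t_end = 10, sample_times = c(0, 20)),
               "within")
  expect_error(simulate_cell(p, t_end = 10, sample_times = c(0, 10),
                             initial_rna = -1), "initial_rna")
})

test_that("no initiation channel keeps counts constant at the initial RNA", {
  p <- transcription_params(k1 = 0)
  tr <- simulate_cell(p, t_end = 75, sample_times = seq(0, 75, 15),
                      seed = 1, initial_rna = 3)
  expect_identical(tr$rna_counts, rep(3L, 6))
  expect_identical(tr$rna_counts[1], tr$initial_rna)
})

test_that("trajectories are reproducible and non-decreasing", {
  p <- transcription_params()
  a <- simulate_cell(p, 75, seq(0, 75, 15), seed = 42, initial_rna = 1)
  b <- simulate_cell(p, 75, seq(0, 75, 15), seed = 42, initial_rna = 1)
  expect_identical(a, b)
  for (s in 1:25) {
    tr <- simulate_cell(p, 75, seq(0, 75, 5), seed = s)
    expect_true(all(diff(tr$rna_counts) >= 0))
    expect_identical(tr$rna_counts[1], tr$initial_rna)
  }
})

test_that("closed-form mean interval matches hand-derived cases", {
  expect_equal(mean_interval_closed_form(params_two_step()), 2)
  expect_equal(mean_interval_closed_form(params_symmetric_lock()), 5)
  # disabled lock channel: k_unlock = Inf identical to k_cc = 0
  p_inf <- transcription_params(k1 = 2, k_minus1 = 0.5, k2 = 0.25,
                                k_cc = 3, k_unlock = Inf)
  p_nocc <- transcription_params(k1 = 2, k_minus1 = 0.5, k2 = 0.25,
                                 k_cc = 0, k_unlock = 1)
  expect_identical(mean_interval_closed_form(p_inf),
                   mean_interval_closed_form(p_nocc))
  # per-initiation locking pays p_lock/k_unlock once per interval
  p_pi <- transcription_params(k1 = 1, k_minus1 = 0, k2 = 1, k_cc = 0,
                               k_unlock = 0.5, lock_mode = "per_initiation",
                               p_lock = 0.5)
  expect_equal(mean_interval_closed_form(p_pi), 1 + 1 + 0.5 / 0.5)
  expect_error(
    mean_interval_closed_form(transcription_params(k_rep_bind = 0.1)),
    "k_rep_bind")
})

test_that("theoretical fractions split the interval and respond to k_unlock", {
  fr <- theoretical_fractions(params_two_step())
  expect_equal(unname(fr), c(0.5, 0.5))
  for (p in decomposition_param_sets())
    expect_equal(sum(theoretical_fractions(p)), 1)
  # decreasing k_unlock strictly increases the pre-commitment fraction
  fracs <- vapply(c(Inf, 1, 0.1, 0.01), function(u) {
    p <- transcription_params(k_unlock = u)
    theoretical_fractions(p)[["t_prior_frac"]]
  }, numeric(1))
  expect_true(all(diff(fracs) > 0))
})

test_that("simulated intervals agree with the closed form (oracle)", {
  for (p in list(params_two_step(), params_symmetric_lock(),
                 decomposition_param_sets()$frac27)) {
    iv <- unlist(lapply(1:20, function(s) simulate_intervals(p, 100, seed = s)))
    cf <- mean_interval_closed_form(p)
    se <- stats::sd(iv) / sqrt(length(iv))
    expect_lt(abs(mean(iv) - cf), 3 * se)
  }
})

test_that("k_unlock = Inf is distributionally equivalent to k_cc = 0", {
  p_inf <- transcription_params(k_cc = 4.7, k_unlock = Inf, rna_delay = 0)
  p_nocc <- transcription_params(k_cc = 0, k_unlock = 1, rna_delay = 0)
  finals <- function(p, seeds) vapply(seeds, function(s) {
    tr <- simulate_cell(p, 75, c(0, 75), seed = s)
    tr$rna_counts[2]
  }, numeric(1))
  a <- finals(p_inf, 1:300)
  b <- finals(p_nocc, 1001:1300)
  expect_gt(ks_compare(a, b)$p_value, 0.01)
})
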