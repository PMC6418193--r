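#' Scenario presets for the synthetic-data generators
#'
#' Documented parameter sets emulating the measured conditions. The rate
#' constants are calibrated (the study's own parameter table is not
#' reproducible from the main text): at the `chromosome_30C` setting the
#' 500-cell population produces on average about 1.9 new RNAs per cell in
#' 60 minutes, and the pre/post-commitment split of the mean initiation
#' interval is roughly 9% / 91%. Lowering temperature is modelled purely as
#' a drop in the unlocking rate; `chromosome_10C` uses a `k_unlock` small
#' enough that locked promoters typically stay locked for the rest of a
#' 75-minute run. `plasmid_any` disables locking (`k_unlock = Inf`): on
#' plasmids the positive and negative supercoils generated by transcription
#' diffuse and annihilate instead of accumulating.
#'
#' @param scenario One of `"chromosome_30C"`, `"chromosome_10C"`,
#'   `"plasmid_any"`.
#' @return A [transcription_params()] object.
#' @export
scenario_params <- function(scenario = c("chromosome_30C", "chromosome_10C",
                                         "plasmid_any")) {
  scenario <- match.arg(scenario)
  switch(scenario,
    chromosome_30C = transcription_params(),
    chromosome_10C = transcription_params(k_unlock = 0.001),
    plasmid_any = transcription_params(k_unlock = Inf))
}

#' Specification for a synthetic cross-sectional count dataset
#'
#' @param scenario Scenario preset name, or `"custom"` (requires `params`).
#' @param params A [transcription_params()] object; required for
#'   `"custom"`, otherwise derived from the scenario.
#' @param n_cells Cells per time point (>= 1).
#' @param sample_times Ascending sampling grid, minutes.
#' @param init_rna_poisson_mean Poisson mean of spurious initial RNAs.
#' @param seed Integer seed.
#' @return An object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(scenario = "chromosome_30C", params = NULL,
                           n_cells = 100, sample_times = seq(0, 75, 15),
                           init_rna_poisson_mean = 0.7, seed = 1L) {
  if (identical(scenario, "custom")) {
    if (is.null(params))
      stop("scenario 'custom' requires explicit params", call. = FALSE)
  } else {
    params <- scenario_params(scenario)
  }
  validate_transcription_params(params)
  if (n_cells < 1) stop("n_cells must be >= 1 at every time point",
                        call. = FALSE)
  if (is.unsorted(sample_times, strictly = TRUE) || min(sample_times) < 0)
    stop("sample_times must be a strictly ascending non-negative grid",
         call. = FALSE)
  structure(list(scenario = scenario, params = params, n_cells = n_cells,
                 sample_times = sample_times,
                 init_rna_poisson_mean = init_rna_poisson_mean,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a cross-sectional single-cell count table
#'
#' Emulates the microscopy measurement design: at each sampling time an
#' independent cohort of cells is taken (new cells from the culture, never
#' the same cell twice), so each cohort is simulated from t = 0 up to its
#' own sampling time and observed once. Counts include Poisson-distributed
#' spurious initial RNAs.
#'
#' @param spec A [synthetic_spec()].
#' @return A [count_table()] with `condition = spec$scenario` and one row
#'   per (time point, cell).
#' @export
generate_count_table <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  rows <- list()
  for (ti in seq_along(spec$sample_times)) {
    ts <- spec$sample_times[ti]
    cohort_seed <- spec$seed + (ti - 1L) * (spec$n_cells + 1L)
    set.seed(cohort_seed)
    init <- stats::rpois(spec$n_cells, spec$init_rna_poisson_mean)
    counts <- vapply(seq_len(spec$n_cells), function(i) {
      if (ts == 0) return(init[i])
      tr <- simulate_cell(spec$params, t_end = ts, sample_times = c(0, ts),
                          seed = cohort_seed + i, initial_rna = init[i])
      tr$rna_counts[2]
    }, numeric(1))
    rows[[ti]] <- data.frame(
      condition = spec$scenario, time_min = ts,
      cell_id = sprintf("t%g_c%04d", ts, seq_len(spec$n_cells)),
      rna_count = as.integer(counts), replicate = "r1",
      stringsAsFactors = FALSE)
  }
  validate_count_table(do.call(rbind, rows))
}

#' Relative mean trajectory of a cross-sectional count table
#'
#' Per-time-point means of a single-condition count table divided by the
#' mean at the last time point, with scaled Student-t confidence-interval
#' halfwidths — the cross-sectional analogue of [relative_to_last()].
#'
#' @param table A single-condition [count_table()].
#' @param ci_level Confidence level (default 0.90).
#' @return A `relative_trajectory` object.
#' @export
relative_trajectory_from_table <- function(table, ci_level = 0.90) {
  table <- validate_count_table(table)
  if (length(unique(table$condition)) != 1)
    stop("expected a single-condition table", call. = FALSE)
  times <- sort(unique(table$time_min))
  per_time <- lapply(times, function(ts)
    summarize_counts(table$rna_count[table$time_min == ts], ci_level))
  means <- vapply(per_time, `[[`, numeric(1), "mean")
  final <- means[length(means)]
  if (final <= 0) stop("zero mean at the final time point", call. = FALSE)
  hw <- vapply(per_time, function(s) (s$ci90[2] - s$ci90[1]) / 2, numeric(1))
  structure(list(sample_times = times, rel_means = means / final,
                 ci90_halfwidths = hw / final),
            class = "relative_trajectory")
}

#' Generate a noisy Lineweaver-Burk dataset with known truth
#'
#' Builds condition points on an exact Lineweaver-Burk line defined by the
#' true pre- and post-commitment durations at the reference condition, then
#' perturbs the inverse rates with multiplicative lognormal noise of a given
#' coefficient of variation. The generating fractions are recorded so
#' recovery can be checked.
#'
#' @param t_prior_ref True mean time prior to commitment at the reference
#'   condition, minutes (> 0).
#' @param t_after_ref True mean time after commitment, minutes (> 0).
#' @param inv_rnap_points Inverse relative RNAP concentrations (default the
#'   0.5X, 1X, 1.5X, 2X series: `c(2, 1, 2/3, 0.5)`).
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0).
#' @param seed Integer seed.
#' @param inv_rnap_ref Reference inverse concentration (default 1, the 1X
#'   control).
#' @return An `lb_dataset` with attribute `truth` (list with
#'   `t_prior_frac`, `t_after_frac`, `slope`, `intercept`).
#' @export
generate_lb_dataset <- function(t_prior_ref, t_after_ref,
                                inv_rnap_points = c(2, 1, 2 / 3, 0.5),
                                noise_cv = 0, seed = 1L, inv_rnap_ref = 1) {
  if (t_prior_ref <= 0 || t_after_ref <= 0)
    stop("true durations must be > 0", call. = FALSE)
  if (noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  slope <- t_prior_ref / inv_rnap_ref
  intercept <- t_after_ref
  inv_rate <- intercept + slope * inv_rnap_points
  if (noise_cv > 0) {
    set.seed(as.integer(seed))
    sdlog <- sqrt(log(1 + noise_cv^2))
    inv_rate <- inv_rate * stats::rlnorm(length(inv_rate),
                                         meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }
  labels <- paste0(round(1 / inv_rnap_points, 3), "X")
  ref_idx <- which.min(abs(inv_rnap_points - inv_rnap_ref))
  ds <- lb_dataset(data.frame(label = labels, inv_rnap = inv_rnap_points,
                              inv_rate = inv_rate, stringsAsFactors = FALSE),
                   reference_index = ref_idx)
  dt <- t_prior_ref + t_after_ref
  attr(ds, "truth") <- list(t_prior_frac = t_prior_ref / dt,
                            t_after_frac = t_after_ref / dt,
                            slope = slope, intercept = intercept)
  ds
}

#' Generate a gene universe with prescribed counts
#'
#' Builds a synthetic genome-wide classification reproducing given totals:
#' `n_genes` genes of which `n_sensitive` are supercoiling-sensitive, a
#' transient cold-shock response set and a long-term cold-shock response
#' set (disjoint) with prescribed sizes and sensitive-gene overlaps. The
#' sensitivity flags outside the two constrained sets are placed uniformly
#' at random.
#'
#' Defaults reproduce the published totals: 4452 genes, 306 sensitive,
#' a 70-gene transient set containing 10 sensitive genes (the only integer
#' count for which 10/70 rounds to the reported ~14%), and a 35-gene
#' long-term set containing none.
#'
#' @param n_genes,n_sensitive Universe totals.
#' @param transient_size,transient_sensitive Transient-set size and its
#'   sensitive overlap.
#' @param longterm_size,longterm_sensitive Long-term-set size and overlap.
#' @param seed Integer seed.
#' @return A [gene_universe()] with sets `"transient"` and `"long_term"`.
#' @export
generate_gene_universe <- function(n_genes = 4452, n_sensitive = 306,
                                   transient_size = 70,
                                   transient_sensitive = 10,
                                   longterm_size = 35,
                                   longterm_sensitive = 0, seed = 1L) {
  if (transient_sensitive > transient_size ||
      longterm_sensitive > longterm_size)
    stop("set overlap exceeds set size", call. = FALSE)
  if (transient_size + longterm_size > n_genes)
    stop("sets exceed the universe", call. = FALSE)
  rest_sensitive <- n_sensitive - transient_sensitive - longterm_sensitive
  rest_size <- n_genes - transient_size - longterm_size
  if (rest_sensitive < 0 || rest_sensitive > rest_size)
    stop("infeasible sensitive counts", call. = FALSE)

  ids <- sprintf("g%04d", seq_len(n_genes))
  transient_ids <- ids[seq_len(transient_size)]
  longterm_ids <- ids[transient_size + seq_len(longterm_size)]
  rest_ids <- ids[-(seq_len(transient_size + longterm_size))]

  sensitive <- stats::setNames(logical(n_genes), ids)
  sensitive[transient_ids[seq_len(transient_sensitive)]] <- TRUE
  if (longterm_sensitive > 0)
    sensitive[longterm_ids[seq_len(longterm_sensitive)]] <- TRUE
  set.seed(as.integer(seed))
  sensitive[sample(rest_ids, rest_sensitive)] <- TRUE

  gene_universe(ids, unname(sensitive),
                set_memberships = list(transient = transient_ids,
                                       long_term = longterm_ids))
}

#' Plain over-dispersed count generator
#'
#' Poisson or negative-binomial draws for unit-testing the count statistics
#' in isolation from the mechanistic simulator.
#'
#' @param n Number of cells.
#' @param mean Mean count.
#' @param cv2 Target squared coefficient of variation; `NULL` or
#'   `1 / mean` gives Poisson, larger values a negative binomial with
#'   matching mean and variance.
#' @param seed Integer seed.
#' @return Integer vector of counts.
#' @export
generate_counts <- function(n, mean, cv2 = NULL, seed = 1L) {
  set.seed(as.integer(seed))
  if (is.null(cv2) || abs(cv2 - 1 / mean) < 1e-12) {
    stats::rpois(n, mean)
  } else {
    if (cv2 <= 1 / mean)
      stop("cv2 below the Poisson floor 1/mean is not representable",
           call. = FALSE)
    size <- mean^2 / (cv2 * mean^2 - mean) # var = mean + mean^2/size
    stats::rnbinom(n, size = size, mu = mean)
  }
}
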