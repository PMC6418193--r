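#' Run the population simulation protocol
#'
#' Simulates `n_cells` independent cells of the initiation model on a fixed
#' sampling grid. Each cell starts with one free promoter, all other
#' species at zero, and an initial RNA count drawn from a Poisson
#' distribution (spurious pre-induction production). Defaults follow the
#' measurement protocol: 500 cells, 75 minutes, samples every 15 minutes,
#' Poisson mean 0.7 RNA/cell.
#'
#' Per-cell seeds are derived as `seed + cell_index` so runs are
#' reproducible and cells are independent.
#'
#' @param params A [transcription_params()] object.
#' @param n_cells Number of cells (>= 1).
#' @param t_end Run length, minutes.
#' @param sample_every Sampling period, minutes; must divide `t_end`.
#' @param init_rna_poisson_mean Mean of the Poisson initial RNA count.
#' @param seed Integer base seed.
#' @return An object of class `population_run`: `params`, `trajectories`
#'   (list of [simulate_cell()] results), `sample_times`, `mean_rna`
#'   (arithmetic mean count per sample time), `seed`.
#' @examples
#' run <- run_protocol(transcription_params(), n_cells = 50, seed = 1)
#' run$mean_rna
#' @export
run_protocol <- function(params, n_cells = 500, t_end = 75,
                         sample_every = 15, init_rna_poisson_mean = 0.7,
                         seed = 1L) {
  validate_transcription_params(params)
  if (n_cells < 1) stop("n_cells must be >= 1", call. = FALSE)
  if (sample_every <= 0 || abs(t_end / sample_every - round(t_end / sample_every)) > 1e-9)
    stop("sample_every must divide t_end", call. = FALSE)
  if (init_rna_poisson_mean < 0)
    stop("init_rna_poisson_mean must be >= 0", call. = FALSE)

  sample_times <- seq(0, t_end, by = sample_every)
  set.seed(as.integer(seed))
  init <- stats::rpois(n_cells, init_rna_poisson_mean)
  trajectories <- lapply(seq_len(n_cells), function(i) {
    simulate_cell(params, t_end, sample_times,
                  seed = as.integer(seed) + i, initial_rna = init[i])
  })
  counts <- do.call(rbind, lapply(trajectories, `[[`, "rna_counts"))
  structure(
    list(params = params, trajectories = trajectories,
         sample_times = sample_times,
         mean_rna = colMeans(counts), seed = as.integer(seed)),
    class = "population_run")
}

# Per-cell count matrix (cells x sample times) of a population_run.
count_matrix <- function(run) {
  do.call(rbind, lapply(run$trajectories, `[[`, "rna_counts"))
}

#' Normalize a population run to its last time point
#'
#' Divides the mean RNA trajectory by its value at the final sample time
#' ("relative to the last time moment") and attaches 90% confidence-interval
#' halfwidths for each mean, from a two-tailed Student's t distribution on
#' the per-cell counts, scaled by the same divisor.
#'
#' @param run A [run_protocol()] result.
#' @param ci_level Confidence level for the per-time intervals (default 0.90).
#' @return An object of class `relative_trajectory`: `sample_times`,
#'   `rel_means` (final element exactly 1), `ci90_halfwidths`.
#' @export
relative_to_last <- function(run, ci_level = 0.90) {
  stopifnot(inherits(run, "population_run"))
  final_mean <- run$mean_rna[length(run$mean_rna)]
  if (final_mean <= 0)
    stop("mean RNA at the final time point is zero: normalization undefined",
         call. = FALSE)
  counts <- count_matrix(run)
  n <- nrow(counts)
  hw <- if (n > 1) {
    tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
    apply(counts, 2, stats::sd) / sqrt(n) * tcrit / final_mean
  } else rep(NA_real_, ncol(counts))
  structure(
    list(sample_times = run$sample_times,
         rel_means = run$mean_rna / final_mean,
         ci90_halfwidths = hw),
    class = "relative_trajectory")
}

#' Scan the promoter unlocking rate against a target trajectory
#'
#' Reproduces the model-fitting protocol: for each candidate `k_unlock` on
#' a (typically log-spaced, descending) grid, a fresh population is
#' simulated and normalized to its last time point, and the sum of squared
#' errors against the target relative trajectory is computed over sample
#' times strictly after zero (the first empirical time point is ignored
#' because induction is not yet fully active there). The grid point with
#' the smallest objective wins.
#'
#' @param base_params [transcription_params()] whose `k_unlock` is replaced
#'   by each grid value in turn.
#' @param k_unlock_grid Non-empty numeric vector, descending; may contain
#'   `Inf` (no locking).
#' @param target A `relative_trajectory` on the same sample-time grid.
#' @param n_cells,t_end,sample_every,init_rna_poisson_mean Protocol
#'   arguments passed to [run_protocol()].
#' @param seed Integer base seed; each grid point uses an independent seed
#'   block `seed + (j - 1) * (n_cells + 1)`.
#' @param weight_by_ci If `TRUE`, squared errors are weighted by
#'   `1 / ci90_halfwidths^2` of the target (times with zero halfwidth get
#'   weight 0).
#' @return An object of class `k_unlock_scan`: `k_unlock_grid`,
#'   `trajectories` (list of `relative_trajectory`), `objective_values`,
#'   `best_k_unlock`.
#' @export
scan_k_unlock <- function(base_params, k_unlock_grid, target,
                          n_cells = 500, t_end = 75, sample_every = 15,
                          init_rna_poisson_mean = 0.7, seed = 1L,
                          weight_by_ci = FALSE) {
  stopifnot(inherits(target, "relative_trajectory"))
  if (length(k_unlock_grid) == 0) stop("k_unlock_grid is empty", call. = FALSE)
  if (is.unsorted(rev(k_unlock_grid)))
    stop("k_unlock_grid must be descending", call. = FALSE)
  sample_times <- seq(0, t_end, by = sample_every)
  if (length(target$sample_times) != length(sample_times) ||
      any(abs(target$sample_times - sample_times) > 1e-9))
    stop("target sample times do not match the protocol grid", call. = FALSE)

  keep <- target$sample_times > 0
  w <- if (weight_by_ci) {
    hw <- target$ci90_halfwidths[keep]
    ifelse(hw > 0, 1 / hw^2, 0)
  } else rep(1, sum(keep))

  trajectories <- vector("list", length(k_unlock_grid))
  objective <- numeric(length(k_unlock_grid))
  for (j in seq_along(k_unlock_grid)) {
    pj <- base_params
    pj$k_unlock <- k_unlock_grid[j]
    validate_transcription_params(pj)
    run <- run_protocol(pj, n_cells = n_cells, t_end = t_end,
                        sample_every = sample_every,
                        init_rna_poisson_mean = init_rna_poisson_mean,
                        seed = as.integer(seed) + (j - 1L) * (n_cells + 1L))
    rel <- relative_to_last(run)
    trajectories[[j]] <- rel
    objective[j] <- sum(w * (rel$rel_means[keep] - target$rel_means[keep])^2)
  }
  best <- which.min(objective)
  structure(
    list(k_unlock_grid = k_unlock_grid, trajectories = trajectories,
         objective_values = objective,
         best_k_unlock = k_unlock_grid[best]),
    class = "k_unlock_scan")
}

#' @export
print.k_unlock_scan <- function(x, ...) {
  cat("k_unlock scan:\n")
  print(data.frame(k_unlock = x$k_unlock_grid, sse = x$objective_values))
  cat(sprintf("best k_unlock: %g\n", x$best_k_unlock))
  invisible(x)
}
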