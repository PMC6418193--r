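#' Build a Lineweaver-Burk dataset from rates and RNAP concentrations
#'
#' Inverts measured RNA production rates and relative RNAP concentrations
#' element-wise into the `(1/RNAP, 1/rate)` points of a Lineweaver-Burk
#' plot. Concentrations are relative to the control ("1X") condition;
#' absolute units are never required.
#'
#' @param rnap_rel_concs Positive relative RNAP concentrations
#'   (e.g. `c(0.5, 1, 1.5, 2)` for the 0.5X-2X media series).
#' @param rna_rates Positive RNA production rates, RNA per minute, same
#'   length.
#' @param reference_label Label of the control condition.
#' @param labels Condition labels (default `"<conc>X"`).
#' @return An object of class `lb_dataset`: data frame `points` with
#'   columns `label`, `inv_rnap`, `inv_rate`, and `reference_index`.
#' @examples
#' build_lb_dataset(c(1, 2), c(0.5, 1), reference_label = "1X")
#' @export
build_lb_dataset <- function(rnap_rel_concs, rna_rates,
                             reference_label = "1X",
                             labels = paste0(rnap_rel_concs, "X")) {
  if (length(rnap_rel_concs) != length(rna_rates))
    stop("concentrations and rates must have equal length", call. = FALSE)
  if (any(rnap_rel_concs <= 0) || any(rna_rates <= 0))
    stop("concentrations and rates must all be > 0", call. = FALSE)
  if (!reference_label %in% labels)
    stop(sprintf("reference label '%s' not among conditions", reference_label),
         call. = FALSE)
  pts <- data.frame(label = labels,
                    inv_rnap = 1 / rnap_rel_concs,
                    inv_rate = 1 / rna_rates,
                    stringsAsFactors = FALSE)
  lb_dataset(pts, which(labels == reference_label)[1])
}

#' @rdname build_lb_dataset
#' @param points Data frame with columns `inv_rnap`, `inv_rate` (and
#'   optionally `label`).
#' @param reference_index Row index of the control condition.
#' @export
lb_dataset <- function(points, reference_index = 1L) {
  stopifnot(is.data.frame(points),
            all(c("inv_rnap", "inv_rate") %in% names(points)))
  if (any(points$inv_rnap <= 0) || any(points$inv_rate <= 0))
    stop("all Lineweaver-Burk coordinates must be > 0", call. = FALSE)
  if (length(unique(points$inv_rnap)) < 2)
    stop("at least 2 distinct inverse-RNAP values are required", call. = FALSE)
  if (reference_index < 1 || reference_index > nrow(points))
    stop("reference_index out of range", call. = FALSE)
  structure(list(points = points,
                 reference_index = as.integer(reference_index)),
            class = "lb_dataset")
}

#' Fit the Lineweaver-Burk line
#'
#' Ordinary least squares of inverse production rate on inverse relative
#' RNAP concentration. The intercept estimates the RNAP-independent time
#' after commitment to open complex formation; the slope times the
#' reference inverse concentration estimates the time prior to commitment.
#'
#' @param data An [lb_dataset()].
#' @param weights Optional non-negative observation weights (unweighted by
#'   default).
#' @return Named numeric vector `c(slope, intercept)` (minutes per RNA).
#' @examples
#' d <- lb_dataset(data.frame(inv_rnap = c(1, 2), inv_rate = c(10, 18)))
#' fit_lb_line(d)
#' @export
fit_lb_line <- function(data, weights = NULL) {
  stopifnot(inherits(data, "lb_dataset"))
  pts <- data$points
  fit <- if (is.null(weights)) {
    stats::lm(inv_rate ~ inv_rnap, data = pts)
  } else {
    stats::lm(inv_rate ~ inv_rnap, data = pts, weights = weights)
  }
  cf <- stats::coef(fit)
  c(slope = unname(cf["inv_rnap"]), intercept = unname(cf["(Intercept)"]))
}

#' Decompose the initiation interval around commitment
#'
#' Given a fitted Lineweaver-Burk line, computes the mean interval between
#' transcription events at the reference condition,
#' `delta_t_ref = intercept + slope * inv_rnap_ref`, and its split into the
#' fraction prior to commitment (`slope * inv_rnap_ref / delta_t_ref`,
#' the RNAP-dependent part) and after commitment
#' (`intercept / delta_t_ref`). The fractions sum to 1 by construction.
#'
#' @param slope,intercept Fitted line coefficients (minutes per RNA).
#' @param inv_rnap_ref Inverse relative RNAP concentration of the reference
#'   condition (> 0; 1 for the control).
#' @return An object of class `lb_decomposition`: `slope`, `intercept`,
#'   `delta_t_ref`, `t_prior_frac`, `t_after_frac`.
#' @examples
#' lb_decompose(slope = 0.27 * 30, intercept = 0.73 * 30, inv_rnap_ref = 1)
#' @export
lb_decompose <- function(slope, intercept, inv_rnap_ref = 1) {
  if (inv_rnap_ref <= 0) stop("inv_rnap_ref must be > 0", call. = FALSE)
  slope <- unname(slope); intercept <- unname(intercept)
  delta_t <- intercept + slope * inv_rnap_ref
  if (delta_t <= 0)
    stop("fitted mean interval is non-positive: non-physical fit",
         call. = FALSE)
  structure(
    list(slope = slope, intercept = intercept, delta_t_ref = delta_t,
         t_prior_frac = slope * inv_rnap_ref / delta_t,
         t_after_frac = intercept / delta_t),
    class = "lb_decomposition")
}

#' @export
print.lb_decomposition <- function(x, ...) {
  cat(sprintf("Initiation interval at reference: %.3f min\n", x$delta_t_ref))
  cat(sprintf("  prior to commitment: %.3f   after commitment: %.3f\n",
              x$t_prior_frac, x$t_after_frac))
  invisible(x)
}

#' Estimate the RNA production rate from a simulated population
#'
#' Mean number of RNAs produced per cell divided by the effective
#' observation window. The window excludes the commitment-to-observation
#' delay, because an RNA committed in the last `rna_delay` minutes is never
#' observed.
#'
#' @param run A [run_protocol()] result (typically with zero initial RNA).
#' @return Rate, RNA per minute.
#' @export
estimate_production_rate <- function(run) {
  stopifnot(inherits(run, "population_run"))
  t_end <- max(run$sample_times)
  window <- t_end - run$params$rna_delay
  if (window <= 0) stop("run shorter than the RNA observation delay",
                        call. = FALSE)
  init <- mean(vapply(run$trajectories, `[[`, numeric(1), "initial_rna"))
  (run$mean_rna[length(run$mean_rna)] - init) / window
}

#' End-to-end decomposition from simulated populations
#'
#' Simulates the initiation model at several relative RNAP concentrations,
#' estimates the RNA production rate at each, fits the Lineweaver-Burk line
#' and decomposes it. Serves as the simulation-side counterpart of
#' [theoretical_fractions()].
#'
#' @param params [transcription_params()]; `rnap_level` is overridden by
#'   each element of `rnap_levels`.
#' @param rnap_levels Relative RNAP concentrations (default the 0.5X-2X
#'   series).
#' @param n_cells Cells per concentration.
#' @param t_end Run length per cell, minutes.
#' @param seed Integer base seed.
#' @return An `lb_decomposition` with attribute `rates` (estimated rates).
#' @export
decompose_from_simulation <- function(params,
                                      rnap_levels = c(0.5, 1, 1.5, 2),
                                      n_cells = 2000, t_end = 150,
                                      seed = 1L) {
  rates <- vapply(seq_along(rnap_levels), function(i) {
    p <- params
    p$rnap_level <- rnap_levels[i]
    run <- run_protocol(p, n_cells = n_cells, t_end = t_end,
                        sample_every = t_end, init_rna_poisson_mean = 0,
                        seed = as.integer(seed) + (i - 1L) * (n_cells + 1L))
    estimate_production_rate(run)
  }, numeric(1))
  ds <- build_lb_dataset(rnap_levels, rates, reference_label = "1X")
  line <- fit_lb_line(ds)
  dec <- lb_decompose(line["slope"], line["intercept"],
                      inv_rnap_ref = ds$points$inv_rnap[ds$reference_index])
  attr(dec, "rates") <- rates
  dec
}
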