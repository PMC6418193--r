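#' Construct and validate a single-cell count table
#'
#' The cross-sectional data container used throughout the pipeline: one row
#' per imaged cell, with its experimental condition, sampling time, and
#' integer RNA count. Counts come from distinct cells at each time point
#' (cells are sampled from the culture, not tracked).
#'
#' @param condition Character/factor vector of condition labels.
#' @param time_min Numeric sampling times, minutes.
#' @param cell_id Cell identifiers (unique within condition and time).
#' @param rna_count Non-negative integer RNA counts.
#' @param replicate Optional replicate labels (default "r1").
#' @return A `data.frame` of class `count_table`.
#' @export
count_table <- function(condition, time_min, cell_id, rna_count,
                        replicate = "r1") {
  df <- data.frame(condition = as.character(condition),
                   time_min = as.numeric(time_min),
                   cell_id = as.character(cell_id),
                   rna_count = rna_count,
                   replicate = as.character(replicate),
                   stringsAsFactors = FALSE)
  validate_count_table(df)
}

#' @rdname count_table
#' @param df A data frame with the `count_table` columns.
#' @export
validate_count_table <- function(df) {
  req <- c("condition", "time_min", "cell_id", "rna_count")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols) > 0)
    stop("count table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (nrow(df) == 0 || !any(nzchar(df$condition)))
    stop("count table has no conditions", call. = FALSE)
  bad <- which(is.na(df$rna_count) | df$rna_count < 0 |
               df$rna_count != round(df$rna_count))
  if (length(bad) > 0)
    stop(sprintf("rna_count must be a non-negative integer (first bad row: %d)",
                 bad[1]), call. = FALSE)
  df$rna_count <- as.integer(df$rna_count)
  if (!"replicate" %in% names(df)) df$replicate <- "r1"
  class(df) <- c("count_table", "data.frame")
  df
}

#' Summary statistics of single-cell RNA counts
#'
#' Computes the mean, the squared coefficient of variation
#' (CV-squared = sample variance / mean-squared, with the n-1 variance
#' denominator), and a two-tailed Student-t confidence interval for the
#' mean (90% by default) — the summary convention used for single-cell RNA
#' number tables.
#'
#' @param counts Integer vector of per-cell counts (length >= 2).
#' @param ci_level Confidence level (default 0.90).
#' @return An object of class `condition_summary`: `n_cells`, `mean`,
#'   `cv2` (`NA` with a flag if the mean is zero), `ci90` (length-2 vector).
#' @examples
#' summarize_counts(c(0, 1, 2, 3))
#' @export
summarize_counts <- function(counts, ci_level = 0.90) {
  if (length(counts) < 2)
    stop("at least 2 cells are required", call. = FALSE)
  if (any(is.na(counts))) stop("counts contain NA", call. = FALSE)
  n <- length(counts)
  m <- mean(counts)
  v <- stats::var(counts)
  cv2 <- if (m > 0) v / m^2 else NA_real_
  tcrit <- stats::qt(1 - (1 - ci_level) / 2, df = n - 1)
  hw <- tcrit * sqrt(v / n)
  structure(
    list(n_cells = n, mean = m, cv2 = cv2,
         cv2_defined = m > 0, ci90 = c(m - hw, m + hw)),
    class = "condition_summary")
}

#' @export
print.condition_summary <- function(x, ...) {
  cat(sprintf("n = %d cells, mean = %.3f RNA/cell, CV2 = %s, CI = [%.3f, %.3f]\n",
              x$n_cells, x$mean,
              if (x$cv2_defined) sprintf("%.3f", x$cv2) else "undefined (mean 0)",
              x$ci90[1], x$ci90[2]))
  invisible(x)
}

#' Two-sample Kolmogorov-Smirnov comparison of count distributions
#'
#' Wraps the two-sample KS test with the significance convention used for
#' RNA-number comparisons: two distributions are called distinguishable
#' when the p-value falls below 0.01. Asymptotic p-values are the default
#' (tied integer counts make exact p-values unavailable anyway for large
#' samples); an exact mode is applied automatically when both samples have
#' fewer than 30 observations and no ties, or can be forced.
#'
#' @param a,b Non-empty integer vectors of per-cell counts.
#' @param alpha Significance threshold (default 0.01).
#' @param exact `NULL` (auto), `TRUE` or `FALSE`; passed to
#'   [stats::ks.test()].
#' @return An object of class `ks_result`: `d_stat`, `p_value`,
#'   `distinguishable`.
#' @export
ks_compare <- function(a, b, alpha = 0.01, exact = NULL) {
  if (length(a) == 0 || length(b) == 0)
    stop("both samples must be non-empty", call. = FALSE)
  if (is.null(exact)) exact <- length(a) < 30 && length(b) < 30
  kt <- suppressWarnings(stats::ks.test(a, b, exact = exact))
  structure(
    list(d_stat = unname(kt$statistic), p_value = unname(kt$p.value),
         distinguishable = unname(kt$p.value) < alpha, alpha = alpha),
    class = "ks_result")
}

#' @export
print.ks_result <- function(x, ...) {
  cat(sprintf("KS D = %.4f, p = %.4g -> %s (alpha = %g)\n",
              x$d_stat, x$p_value,
              if (x$distinguishable) "distinguishable" else "not distinguishable",
              x$alpha))
  invisible(x)
}

#' Fold change of mean counts across an induction series
#'
#' Ratio of the mean count at the maximal inducer dose to the mean at zero
#' dose.
#'
#' @param induction Named list mapping numeric dose (as names, e.g. `"0"`,
#'   `"1000"`) to integer count vectors; at least two doses.
#' @return Dimensionless fold change.
#' @examples
#' fold_change(list(`0` = c(0, 1), `1000` = c(2, 3)))
#' @export
fold_change <- function(induction) {
  if (length(induction) < 2) stop("need at least 2 doses", call. = FALSE)
  doses <- as.numeric(names(induction))
  if (any(is.na(doses))) stop("dose names must be numeric", call. = FALSE)
  if (!any(doses == 0)) stop("a zero dose is required", call. = FALSE)
  m0 <- mean(induction[[which(doses == 0)[1]]])
  mmax <- mean(induction[[which.max(doses)]])
  if (m0 == 0) stop("zero-dose mean is zero: fold change undefined",
                    call. = FALSE)
  mmax / m0
}

#' Condition means relative to a reference condition
#'
#' Divides every condition's mean count by the reference condition's mean
#' ("relative mean to the reference case") and scales the Student-t
#' confidence intervals by the same factor.
#'
#' @param table A [count_table()].
#' @param reference_condition Label of the reference condition.
#' @param ci_level Confidence level (default 0.90).
#' @return A data frame with columns `condition`, `n`, `rel_mean`,
#'   `ci_lo`, `ci_hi`.
#' @export
relative_means <- function(table, reference_condition, ci_level = 0.90) {
  table <- validate_count_table(table)
  conds <- unique(table$condition)
  if (!reference_condition %in% conds)
    stop(sprintf("reference condition '%s' not present", reference_condition),
         call. = FALSE)
  ref_mean <- mean(table$rna_count[table$condition == reference_condition])
  if (ref_mean <= 0)
    stop("reference condition mean must be > 0", call. = FALSE)
  rows <- lapply(conds, function(cc) {
    s <- summarize_counts(table$rna_count[table$condition == cc], ci_level)
    data.frame(condition = cc, n = s$n_cells,
               rel_mean = s$mean / ref_mean,
               ci_lo = s$ci90[1] / ref_mean, ci_hi = s$ci90[2] / ref_mean,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Per-condition summary table
#'
#' Applies [summarize_counts()] to each (condition, time) stratum of a
#' count table.
#'
#' @param table A [count_table()].
#' @param by Columns to stratify on (default condition and time).
#' @param ci_level Confidence level.
#' @return A data frame with one row per stratum: `condition`, `time_min`,
#'   `n`, `mean`, `cv2`, `ci90_lo`, `ci90_hi`.
#' @export
summarize_count_table <- function(table, by = c("condition", "time_min"),
                                  ci_level = 0.90) {
  table <- validate_count_table(table)
  key <- interaction(table[by], drop = TRUE)
  rows <- lapply(split(seq_len(nrow(table)), key), function(idx) {
    s <- summarize_counts(table$rna_count[idx], ci_level)
    out <- table[idx[1], by, drop = FALSE]
    out$n <- s$n_cells; out$mean <- s$mean; out$cv2 <- s$cv2
    out$ci90_lo <- s$ci90[1]; out$ci90_hi <- s$ci90[2]
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
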