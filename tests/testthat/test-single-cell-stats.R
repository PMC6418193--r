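test_that("summarize_counts computes mean, CV2 and Student-t CI", {
  s <- summarize_counts(c(2, 2, 2, 2))
  expect_equal(s$mean, 2)
  expect_equal(s$cv2, 0)
  expect_equal(s$ci90, c(2, 2))

  s2 <- summarize_counts(c(0, 1, 2, 3))
  expect_equal(s2$mean, 1.5)
  expect_equal(s2$cv2, (5 / 3) / 2.25)
  hw <- qt(0.95, 3) * sqrt((5 / 3) / 4)
  expect_equal(s2$ci90, c(1.5 - hw, 1.5 + hw))

  expect_error(summarize_counts(c(1)), "2 cells")
  s0 <- summarize_counts(c(0, 0, 0))
  expect_true(is.na(s0$cv2))
  expect_false(s0$cv2_defined)
})

test_that("CV2 of Poisson counts follows the 1/mean relation", {
  x <- generate_counts(5000, mean = 2, seed = 11)
  s <- summarize_counts(x)
  expect_lt(abs(s$cv2 - 0.5), 0.05)
  # negative binomial generator hits a requested over-dispersion
  y <- generate_counts(5000, mean = 2, cv2 = 2, seed = 12)
  expect_lt(abs(summarize_counts(y)$cv2 - 2), 0.3)
  expect_error(generate_counts(10, mean = 2, cv2 = 0.1), "Poisson floor")
})

test_that("locking inflates CV2 of final counts at matched parameters", {
  finals <- function(u, seed0) vapply(1:800, function(s) {
    tr <- simulate_cell(transcription_params(k_unlock = u), 75, c(0, 75),
                        seed = seed0 + s)
    tr$rna_counts[2]
  }, numeric(1))
  cv2 <- function(x) var(x) / mean(x)^2
  expect_gt(cv2(finals(0.005, 3000)), cv2(finals(Inf, 6000)))
})

test_that("ks_compare applies the p < 0.01 convention", {
  ident <- ks_compare(c(0, 1, 2, 2, 3), c(0, 1, 2, 2, 3))
  expect_equal(ident$d_stat, 0)
  expect_equal(ident$p_value, 1)
  expect_false(ident$distinguishable)

  disj <- ks_compare(rep(0L, 200), rep(5L, 200))
  expect_equal(disj$d_stat, 1)
  expect_true(disj$distinguishable)

  expect_error(ks_compare(integer(0), 1:3), "non-empty")
})

test_that("KS type-I error at the 0.01 convention stays below 0.03", {
  fp <- 0
  for (i in 1:100) {
    set.seed(2000 + i); a <- rpois(500, 1.5)
    set.seed(5000 + i); b <- rpois(500, 1.5)
    if (ks_compare(a, b)$distinguishable) fp <- fp + 1
  }
  expect_lte(fp, 3)
})

test_that("fold_change is the max-dose over zero-dose mean ratio", {
  expect_equal(fold_change(list(`0` = c(0, 1), `1000` = c(2, 3))), 5)
  expect_equal(fold_change(list(`0` = c(2, 2), `500` = c(2, 2))), 1)
  expect_error(fold_change(list(`0` = c(0, 0), `1000` = c(1, 1))),
               "undefined")
  expect_error(fold_change(list(`0` = c(1, 2))), "2 doses")
})

test_that("simulated dose responses saturate at high inducer", {
  # dose modulates repressor binding: k_rep_bind = 2 / (1 + dose / 50)
  doses <- c(0, 50, 250, 1000)
  means <- vapply(doses, function(d) {
    p <- transcription_params(k_cc = 0, k_unlock = Inf,
                              k_rep_bind = 2 / (1 + d / 50),
                              k_rep_unbind = 0.05)
    mean(vapply(1:300, function(s) {
      simulate_cell(p, 60, c(0, 60), seed = 7000 + 400 * d + s)$rna_counts[2]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > -2 * 0.1)) # monotone non-decreasing (2 SE)
  # saturation: later doubling of dose adds less than the first induction step
  expect_lt(means[4] - means[3], means[2] - means[1])
})

test_that("relative_means rescales conditions against the reference", {
  tab <- count_table(condition = rep(c("a", "b"), each = 4),
                     time_min = 60, cell_id = 1:8,
                     rna_count = c(1, 1, 1, 1, 2, 2, 2, 2))
  rel <- relative_means(tab, "a")
  expect_equal(rel$rel_mean[rel$condition == "a"], 1)
  expect_equal(rel$rel_mean[rel$condition == "b"], 2)
  expect_error(relative_means(tab, "missing"), "not present")

  # invariance under a common positive scaling of all counts
  tab3 <- tab; tab3$rna_count <- tab3$rna_count * 3L
  rel3 <- relative_means(tab3, "a")
  expect_equal(rel3$rel_mean, rel$rel_mean)
  expect_equal(rel3$ci_hi - rel3$ci_lo, rel$ci_hi - rel$ci_lo)
})
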