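# independent oracle: explicit binomial summation
binom_tail_sum <- function(n, k, p, tail) {
  ks <- if (tail == "ge") k:n else 0:k
  sum(choose(n, ks) * p^ks * (1 - p)^(n - ks))
}

test_that("exact_binomial_tail matches explicit summation", {
  expect_equal(exact_binomial_tail(10, 1, 0, "ge"), 0)
  expect_equal(exact_binomial_tail(10, 0, 0, "ge"), 1)
  p0 <- 306 / 4452
  expect_equal(exact_binomial_tail(35, 0, p0, "le"),
               binom_tail_sum(35, 0, p0, "le"))
  expect_equal(exact_binomial_tail(35, 0, p0, "le"), 0.0827, tolerance = 1e-3)
  expect_equal(exact_binomial_tail(70, 10, p0, "ge"),
               binom_tail_sum(70, 10, p0, "ge"))
  expect_equal(exact_binomial_tail(70, 10, p0, "ge"), 0.0210, tolerance = 1e-2)
  expect_error(exact_binomial_tail(10, 11, 0.5), "k_obs")
  expect_error(exact_binomial_tail(10, 2, 1.5), "probability")
})

test_that("bootstrap_null has the binomial mean and is seed-reproducible", {
  u <- generate_gene_universe(seed = 1)
  d1 <- bootstrap_null(u, 70, n_resamples = 10000, seed = 9)
  expect_lt(abs(mean(d1) - 70 * 306 / 4452), 0.1)
  d2 <- bootstrap_null(u, 70, n_resamples = 10000, seed = 9)
  expect_identical(d1, d2)

  all_sens <- gene_universe(letters[1:5], rep(TRUE, 5))
  expect_true(all(bootstrap_null(all_sens, 3, 100, seed = 1) == 3))
  expect_error(bootstrap_null(u, 0, 10), "set_size")
})

test_that("enrichment_test reproduces the cold-shock set analyses", {
  u <- generate_gene_universe(seed = 1)

  tr <- enrichment_test(u, "transient", n_resamples = 10000, seed = 2)
  expect_equal(tr$observed_sensitive, 10)
  expect_equal(tr$observed_frac, 10 / 70)       # ~14%
  expect_equal(tr$baseline_frac, 306 / 4452)    # ~7%
  expect_equal(tr$tail, "ge_observed")
  mc <- 4 * sqrt(tr$exact_p * (1 - tr$exact_p) / tr$n_resamples)
  expect_lt(abs(tr$boot_p - tr$exact_p), mc)

  lt <- enrichment_test(u, "long_term", n_resamples = 10000, seed = 2)
  expect_equal(lt$observed_sensitive, 0)
  expect_equal(lt$tail, "le_observed")
  expect_equal(lt$exact_p, exact_binomial_tail(35, 0, 306 / 4452, "le"))
  expect_lt(abs(lt$boot_p - lt$exact_p),
            4 * sqrt(lt$exact_p * (1 - lt$exact_p) / lt$n_resamples))

  # strict vs inclusive tail changes the transient answer materially
  tr_strict <- enrichment_test(u, "transient", n_resamples = 10000,
                               seed = 2, tail_mode = "strict")
  expect_equal(tr_strict$exact_p, exact_binomial_tail(70, 11, 306 / 4452, "ge"))
  expect_lt(tr_strict$boot_p, tr$boot_p)

  expect_error(enrichment_test(u, "nope"), "unknown")
})

test_that("a set matching the baseline composition is unremarkable", {
  u <- generate_gene_universe(seed = 1)
  # pick 100 genes with 7 sensitive (~ the 6.9% baseline)
  sens_ids <- u$gene_ids[u$sensitive]
  insens_ids <- setdiff(u$gene_ids, sens_ids)
  u$set_memberships$central <- c(sens_ids[101:107], insens_ids[201:293])
  res <- enrichment_test(u, "central", n_resamples = 5000, seed = 3)
  expect_gt(res$boot_p, 0.3)
})

test_that("results depend only on counts, not on gene labels", {
  u <- generate_gene_universe(seed = 1)
  perm <- sample(length(u$gene_ids))
  u2 <- gene_universe(paste0("x", seq_along(u$gene_ids)),
                      u$sensitive[perm],
                      list(transient = paste0("x", which(perm %in%
                        match(u$set_memberships$transient, u$gene_ids)))))
  r1 <- enrichment_test(u, "transient", n_resamples = 4000, seed = 4)
  r2 <- enrichment_test(u2, "transient", n_resamples = 4000, seed = 4)
  expect_equal(r2$observed_sensitive, r1$observed_sensitive)
  expect_equal(r2$baseline_frac, r1$baseline_frac)
  expect_equal(r2$boot_p, r1$boot_p)
})

test_that("boot_p converges to exact_p as resamples grow", {
  u <- generate_gene_universe(seed = 1)
  exact <- exact_binomial_tail(70, 10, 306 / 4452, "ge")
  for (n in c(1000, 10000, 100000)) {
    r <- enrichment_test(u, "transient", n_resamples = n, seed = 5)
    expect_lt(abs(r$boot_p - exact), 4 * sqrt(exact * (1 - exact) / n))
  }
})
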