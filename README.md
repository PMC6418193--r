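# promlock

Stochastic modelling and statistics for **supercoiling-mediated promoter
locking** in bacterial transcription.

## The scientific problem

A lac-derived promoter integrated into the *E. coli* chromosome becomes
weak *and* noisy at critically low temperatures, while the same promoter
on a single-copy plasmid does not. The mechanistic explanation this
package operationalizes: transcription generates positive supercoiling
ahead of the polymerase; on topologically constrained chromosomal DNA it
accumulates and can trap the promoter in an inactive **locked** state,
and escape from that state (rate `k_unlock`, gyrase-mediated in vivo)
slows as temperature drops.

`promlock` is for researchers in stochastic gene expression who want to
simulate, fit and test this class of models against single-cell RNA-count
data, and to relate supercoiling sensitivity to genome-wide response
classes.

## The model

One promoter copy per cell, four states:

```
OFF_repressed  --k_rep_unbind-->  ON_free        (repressor switching)
ON_free        --k1·R--------->   CLOSED_complex (RNAP binding, R = relative RNAP level)
CLOSED_complex --k_minus1----->   ON_free        (closed-complex dissociation)
CLOSED_complex --k2----------->   ON_free + RNA appears at t + rna_delay
ON_free        --k_cc--------->   LOCKED         (supercoiling buildup)
LOCKED         --k_unlock----->   ON_free        (Inf disables locking)
```

Under full induction the mean interval between transcription events has
the closed form

    Δt = (1 + k₋₁/k₂) · 1/(k₁R) · (1 + k_cc/k_unlock) + 1/k₂

whose RNAP-independent part `1/k₂` is the mean time **after** commitment
to open complex formation, and the rest the time **prior** to it — the
same split a Lineweaver–Burk plot of `1/rate` against `1/R` estimates
from data (intercept vs slope). The simulator is an exact direct-method
SSA with delayed RNA appearance events, compiled via Rcpp, and is tested
against this closed form.

Modules:

* `transcription_params()`, `simulate_cell()`, `simulate_intervals()`,
  `mean_interval_closed_form()`, `theoretical_fractions()` — model + engine.
* `run_protocol()`, `relative_to_last()`, `scan_k_unlock()` — the
  500-cell / 75-min / 15-min population protocol and the one-dimensional
  `k_unlock` fit.
* `summarize_counts()`, `ks_compare()`, `fold_change()`,
  `relative_means()` — single-cell count statistics (CV², 90% Student-t
  CIs, KS at the p < 0.01 convention).
* `build_lb_dataset()`, `fit_lb_line()`, `lb_decompose()`,
  `decompose_from_simulation()` — initiation-interval decomposition.
* `gene_universe()`, `bootstrap_null()`, `exact_binomial_tail()`,
  `enrichment_test()` — cold-shock gene-set enrichment bootstrap.
* `scenario_params()`, `generate_count_table()`, `generate_lb_dataset()`,
  `generate_gene_universe()` — synthetic data with known ground truth.
* `read_count_table()`, `read_model_config()`, `run_pipeline()`,
  `promlock_cli()` (+ `inst/cli/promlock`) — I/O, config, CLI.

## Worked example

```r
library(promlock)

p <- scenario_params("chromosome_30C")   # calibrated defaults
mean_interval_closed_form(p)             # 31.4 min between RNAs
theoretical_fractions(p)                 # 0.091 prior / 0.909 after commitment

run <- run_protocol(p, n_cells = 500, seed = 1)
round(run$mean_rna, 2)
#> [1] 0.66 1.10 1.60 2.07 2.57 3.06     # ~1.9 new RNAs by 60 min + 0.7 initial

# fit k_unlock to a cold-condition target trajectory
target <- relative_to_last(
  run_protocol(scenario_params("chromosome_10C"), n_cells = 2000, seed = 2))
scan_k_unlock(p, c(1, 0.25, 0.0625, 0.015625, 0.00390625, 0.001),
              target, seed = 3)
#> best k_unlock: 0.00390625               # locks outlasting the 75-min run

# end-to-end Lineweaver-Burk decomposition from simulated populations
decompose_from_simulation(p, n_cells = 2000, t_end = 150, seed = 4)
#> Initiation interval at reference: 31.982 min
#>   prior to commitment: 0.077   after commitment: 0.923

# cold-shock gene sets vs supercoiling sensitivity
u <- generate_gene_universe(seed = 1)    # 4452 genes, 306 sensitive (6.9%)
enrichment_test(u, "transient", seed = 5)
#> Set 'transient' (70 genes): 10 sensitive (14.3%) vs baseline 6.9%
#>   tail ge_observed (inclusive): bootstrap p = 0.0238 (n = 10000), exact p = 0.0210
enrichment_test(u, "long_term", seed = 5)
#> Set 'long_term' (35 genes): 0 sensitive (0.0%) vs baseline 6.9%
#>   tail le_observed (inclusive): bootstrap p = 0.0817 (n = 10000), exact p = 0.0827
```

Reading the numbers: the transient cold-shock set is about twice as
likely as a random gene to be supercoiling-sensitive (14.3% vs 6.9%,
chance probability ≈ 2%), while the long-term set contains none
(depletion probability ≈ 8%). The fitted `k_unlock` for the cold
condition is ~250× smaller than the warm value — locked promoter states
outlast the measurement, which is what flattens the RNA trajectory and
inflates CV² across cells.

## Command line

```sh
Rscript inst/cli/promlock synth genes --out-dir out --seed 1
Rscript inst/cli/promlock enrich --genes out/gene_universe.tsv \
        --set transient --resamples 10000 --seed 1 --out-dir out
Rscript inst/cli/promlock run --out-dir out --seed 1     # full pipeline
```

See `vignettes/promoter-locking.Rmd` for the model derivation, parameter
calibration, conventions (tails, variances, CI levels) and limitations.
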