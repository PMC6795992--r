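# tdrpclock

Time-calibrating viral phylogenies under the **time-dependent rate
phenomenon (TDRP)**: measured evolutionary rates decay as the timescale of
measurement grows, so no constant- or relaxed-clock rate converts
substitutions into time correctly across deep virus–host co-speciation
histories. For viruses such as simian foamy viruses, whose divergences
mirror dated host divergences over tens of millions of years, the decay is
well described by a power law between a node's age *t* (Myr) and its height
*s* (substitutions/site from the node to its tips):

```
log t = α + β log s
```

`tdrpclock` fits this clock per posterior tree — extracting calibration-clade
heights, pairing each with a fresh host-date draw
t ~ N(median, σ_t) truncated to t > 0, with
σ_t = max((median − lower)/1.96, (upper − median)/1.96) from the reported
95% interval — and predicts the ages of target clades in the same tree.
Pooled across the posterior sample, target ages are summarised by the median
and 95% highest-posterior-density (HPD, shortest-window) interval, so
phylogenetic and host-date uncertainty propagate jointly.

The package also covers the surrounding analysis stages for a
recombination-structured genome:

* **consensus filtering** of recombination-event calls (keep events
  supported by ≥ 4 programmes at P < 0.05) and single-linkage
  **breakpoint clustering** into hotspots;
* **hotspot-bounded alignment splitting** with per-sequence excision
  (blanking with gaps over 1-based inclusive coordinates, preserving column
  homology);
* **site-rate scaling** to a global mean of 1, per-region means with
  posterior HPDs, and focal/complement **rate ratios** with linear- and
  log-scale HPDs;
* **codon-usage comparison**: pooled sense-codon counts per group and a
  Pearson χ² on the fixed 61-row table, df = (61−1)(G−1);
* **simulators with known ground truth** for every input (posterior tree
  sets, region-structured alignments, site-rate matrices) and a
  **coverage experiment** that verifies the 95% HPDs are calibrated;
* a config-driven, manifest-writing **pipeline** (`run_pipeline()`).

All user-facing functions take data frames and return tibbles; fitted
objects support `tidy()`, `glance()` and `autoplot()`. Trees are `ape`
`phylo` objects.

## Worked example

Simulate a 500-tree posterior from the demo host geometry (true clock
α = 4.114, β = 1.762; mandrill North–South split at 1.1 Myr, basal Old
World monkey and ape SFV diversification at 30 Myr), then date the two
target clades from three host calibrations (5.3, 8.6 and 100 Myr):

```r
library(tdrpclock)

spec <- demo_sim_spec(n_trees = 500, sigma = 0.1)
sim  <- simulate_posterior_trees(spec, seed = 1)
fit  <- run_dating(sim$trees, demo_calibration(), demo_targets(), seed = 2)
fit
#> Power-law TDRP clock fit over 500 posterior trees (0 skipped)
#>   alpha = 4.118 (95% HPD = 3.845-4.415), beta = 1.747 (95% HPD = 1.456-2.037)
#>   log space: natural; time unit: Myr
#> # A tibble: 2 × 5
#>   clade       median hpd_lower hpd_upper n_draws
#>   <chr>        <dbl>     <dbl>     <dbl>   <int>
#> 1 mandrill-NS   1.15     0.560      1.91     500
#> 2 OWMA-SFV     31.0     18.5       44.7      500
```

The fitted clock recovers the generating parameters (medians 4.118 and
1.747 against truth 4.114 and 1.762), and both target ages sit near their
true values with HPDs reflecting the joint height and date uncertainty.
`tdrp_report(fit)` returns the same table for export; `autoplot(fit)` draws
the pooled age densities with their HPD bounds.

Splitting an envelope-gene-like alignment at its two recombination
hotspots:

```r
hotspots <- tibble::tibble(name = c("RH5", "RH3"),
                           start = c(631, 1369), end = c(768, 1521))
regions <- split_alignment(aln, hotspots,
                           region_names = c("env_LP5SU", "env_cenSU", "env_3SUTM"))
# 2,883 columns -> regions of 630, 600 and 1,362 columns
```

See the methods vignette (`vignettes/tdrp-cospeciation-dating.Rmd`) for the
model, its assumptions, the simulator design and the coverage-experiment
rationale.

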