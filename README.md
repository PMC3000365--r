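# cagdyn

Quantitative analysis of somatic CAG trinucleotide-repeat instability from
fragment-analysis (capillary electrophoresis) traces, for researchers
working with Huntington's-disease mouse models or other expanded-STR
systems.

In HD model mice the expanded CAG tract (~119 repeats in the founder line
this package is parameterised for) keeps changing length somatically, and
it does so in two distinct modes:

* **Continuous drift** (tail and other peripheral tissues): a daily
  Bernoulli walk per DNA tract — expansion by one repeat with probability
  `p_e` per tract per day, contraction with `p_c` — whose moments are
  `mu(t) = mu0 + (p_e - p_c) t` and
  `sigma^2(t) = sigma0^2 + (p_e + p_c) t`. Inverting these equations on
  the observed mean/variance change between two ages yields `p_e` and
  `p_c`.
* **Periodic expansion** (striatum, cortex): stochastic insertion of a
  consistent ~7-repeat fragment into a fraction of tracts, producing a
  ladder of regularly spaced peaks. Peak intervals, and peak areas
  rescaled to the ~10,000 cells of a sample, yield the insertion length
  distribution, the non-expanding fraction, the total insertion count and
  the per-tract event rate.

The package provides:

* a trace data model with delimited-text I/O and the bp-to-repeat
  conversion `mu_t = (mu_m - 86)/3` (86 bp flank);
* `decompose()` — masked Nelder–Mead fitting of consecutive normal
  distributions until ≥98% of the raw trace area is accounted for,
  returning a classed model object with `print`/`summary`/`coef`/
  `predict`/`plot`/`residuals` methods;
* `estimate_drift()` / `predict_drift()` / `genomewide_rate()` — the
  drift-equation inversion and its genome-wide extrapolation;
* `peak_intervals()`, `interval_stats()` (with the ≥12-repeat doublet
  cutoff), `area_proportions()`, `nonexpanding_fraction()`,
  `total_insertions()`, `periodic_event_rate()` — the periodicity
  estimators;
* forward Monte Carlo simulators for the unitary walk, periodic
  insertion, their combination, and an error-prone PCR branching process,
  all bit-reproducible under integer seeds;
* a synthetic cohort generator (`render_trace()`, `generate_cohort()`)
  emulating PCR broadening, length-dependent amplification attenuation
  and multi-tissue study designs, used throughout the tests as ground
  truth;
* batch entry points `cmd_fit()` / `cmd_analyze()` / `cmd_simulate()` and
  a thin Rscript front end in `inst/cli/cagdyn.R`.

See `vignettes/cag-instability-methods.Rmd` for the models, parameter
defaults and design decisions.

## Worked example

```r
library(cagdyn)

# invert the drift equations on the tail cohort moments
# (median expansion 1.97 repeats, sigma 1.98 -> 2.87, 119 days)
est <- estimate_drift(mu_start = 119, mu_end = 120.97,
                      sigma_start = 1.98, sigma_end = 2.87,
                      elapsed_days = 119)
est
#> <drift_params> p_e = 0.02641, p_c = 0.009859 (total 0.03627 events/tract/day)
genomewide_rate(est$p_e + est$p_c)
#> [1] 251896.6

# forward-simulate a striatum-like sample and take it back apart
pop <- simulate_periodic(tract_population(119, n_tracts = 10000),
                         periodic_params(event_prob = 0.018), days = 126,
                         seed = 42)
trace <- render_trace(pop, trace_render_config(attenuation = 1))
fit <- decompose(trace)
fit
#> <peak_decomposition> 7 peak(s), explained 0.9907
#>  mean_bp sigma_bp amplitude     area mean_repeats area_fraction
#>  442.998  5.93842   69.6491 1036.755      118.999     0.1041853
#>  464.001  6.04728  156.0036 2364.746      126.000     0.2376373
#>  484.999  6.14633  170.8871 2632.784      133.000     0.2645729
#>  505.994  6.25685  127.4434 1998.770      139.998     0.2008598
#>  527.049  6.40518   73.6618 1182.669      147.016     0.1188484
#>  547.363  5.86521   28.6229  420.811      153.788     0.0422880
#>  567.668 12.29170   10.2086  314.536      160.556     0.0316082
```

The fitted peaks sit on the 7-repeat ladder (119, 126, 133, ... repeats,
21 bp apart). The first peak's share is the fraction of tracts still at
the founder length after 126 days at 0.018 events/tract/day
(`P(no event) = (1 - 0.018)^126 ≈ 0.10`), and the area-weighted insertion
count recovers the simulated total:

```r
props <- area_proportions(fit)
nonexpanding_fraction(props)
#> [1] 0.1041853
total_insertions(props)
#> [1] 22458.46
interval_stats(peak_intervals(fit))[c("mean", "median")]
#> $mean
#> [1] 6.926098
#> $median
#> [1] 6.998819
```

(Simulated truth for this seed: 10,000 tracts x mean 2.27 events ≈ 22,600
insertions; interval truth exactly 7.)

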