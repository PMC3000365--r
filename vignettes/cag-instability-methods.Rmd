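---
title: "Models and methods for somatic CAG-repeat instability analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for somatic CAG-repeat instability analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cagdyn)
```

## The measurement and its model

In Huntington's disease model mice carrying an expanded CAG tract
(~119 repeats in the founder line this package is parameterised for), the
repeat length changes somatically over the animal's life, and it changes
differently in different tissues. The data the package analyses are
fragment-analysis electropherograms: fluorescence intensity against
PCR-amplicon size in bp, one trace per tissue sample. A sample contains on
the order of 10,000 cells, so a trace is a population readout -- the
convolution of the distribution of true repeat lengths across cells with
the measurement spread introduced by PCR slippage.

Two unit conversions anchor everything. The CAG tract sits inside an 86 bp
flank, so a fragment of mean size $\mu_m$ bp carries
$\mu_t = (\mu_m - 86)/3$ repeats (`repeats_from_size()`,
`size_from_repeats()`). All statistics are quoted in repeat units; fitted
peak parameters are kept in bp.

## Peak decomposition

`decompose()` models a trace as a sum of consecutive normal distributions,
one per repeat-length class present in the sample:

1. **Greedy masked fitting.** The highest lobe of the current residual is
   located (ties broken toward lower bp); a starting $\sigma$ comes from
   the narrower one-sided half-width at half maximum, so the shoulder of an
   overlapping neighbour does not inflate it. One Gaussian is fitted by
   Nelder--Mead simplex (least squares, parameters mean / log sigma /
   log amplitude, relative tolerance $10^{-12}$, at most 2000 iterations)
   to a window covering the contiguous lobe, clipped to $\pm 4\sigma$
   estimates; the rest of the trace is masked. Failed fits are restarted
   up to 3 times with 10% parameter jitter drawn from a seedable stream.
2. **Joint refinement after every added component.** The greedy fit of one
   component is always contaminated by its neighbours, so after each
   addition all components are re-optimised together by bounded
   Levenberg--Marquardt least squares with the analytic Jacobian.
   Component $\sigma$ is constrained to a band (0.4x to 2x) around the
   median component width: the components represent PCR-broadened length
   classes of similar width, and an unbounded fit will happily stretch one
   Gaussian across several small classes.
3. **Stopping rule.** Components are added until the fitted curve accounts
   for at least 98% of the raw trace area, measured as
   $1 - \int |y - \hat y| \,/ \int y$. We deliberately do not use the bare
   model-to-data area ratio: a single broad Gaussian can match the total
   area of a multi-peak trace while fitting it badly, and the coverage
   form is 1 exactly when the fit is exact. The plain area ratio is kept
   as the `area_ratio` field. If `max_peaks` (default 12) is reached
   first, the result is flagged, not thrown.
4. **Cleanup.** Components contributing less than 1% of the fitted area
   are dropped as noise (and the rest re-refined); two components closer
   than the narrower one's $\sigma$ are merged, since they are not
   mutually resolvable and describe one class split in two.

On noiseless renders of up to six well-separated components the procedure
recovers component count, means to better than 0.1 bp and area fractions
to well under 2%; the test suite pins this down. Tail-type traces are
single-peaked and are fitted with `fit_single_gaussian()`.

The greedy-then-refine schedule is a reconstruction: the sequential masked
simplex fit is the named method, but nothing fixes whether refinement
followed the masking or how. On clean data the orders are
indistinguishable; refining after every addition is what makes the 98%
stopping rule meaningful, so that is the schedule implemented.

## The continuous (tail-type) drift model

Peripheral tissues show a single peak that drifts up and broadens. The
model is a daily Bernoulli walk per tract: each day a tract gains one
repeat with probability $p_e$, loses one with probability $p_c$, else is
unchanged (events mutually exclusive within a day, $\Delta t$ = 1 day).
The moments after $t$ days are

$$\mu(t) = \mu_0 + (p_e - p_c)\,t, \qquad
  \sigma^2(t) = \sigma_0^2 + (p_e + p_c)\,t,$$

implemented in `predict_drift()` and inverted exactly by
`estimate_drift()`:

$$p_e = \tfrac12\!\left(\frac{\Delta\sigma^2}{T} + \frac{\Delta\mu}{T}\right),
\qquad
p_c = \tfrac12\!\left(\frac{\Delta\sigma^2}{T} - \frac{\Delta\mu}{T}\right).$$

The variance form drops the second-order term of the exact per-step
variance $(p_e + p_c) - (p_e - p_c)^2$; `exact_step_variance()` exposes the
gap, the tests assert it, and the simulators use the exact dynamics. For
the reference tail comparison (median expansion 1.97 repeats, $\sigma$
1.98 $\to$ 2.87 between the 3- and 21-week samplings) the inversion gives
$p_e \approx 0.026$, $p_c \approx 0.010$, $\approx 0.036$ events per tract
per day in total.

**Elapsed time: 119 vs 126 days.** The 3-to-21-week interval is nominally
18 weeks = 126 days, but only $T = 119$ days (17 weeks, i.e. ages taken
mid-week or biopsy-to-sacrifice timing) reproduces 0.026/0.010/0.036 from
the printed moments; 126 days gives 0.025/0.009/0.034. The package
defaults to 119 days for this inversion and leaves `elapsed_days` a free
argument. For the periodic event-rate denominator (below) the reverse
holds: 126 days is what reproduces the quoted 0.018, so that operation
defaults to 126.

`genomewide_rate()` extrapolates a per-tract rate to the whole genome as
`rate * genome_nt / tract_nt` with defaults 360 nt (a ~120-repeat CAG
tract) and 2.5 Gb: 0.036 scales to 250,000 events per cell per day. The
analogous periodic figure computes to 125,000 (= 0.018 x 2.5e9/360); the
package reports the computed value and makes no attempt to force the
rounder "~100,000" sometimes quoted for it.

## The periodic (striatum/cortex-type) model

Brain tissues show a retained founder peak plus regularly spaced later
peaks: a fraction of cells undergoes stochastic insertion of a
consistent-length (~7 repeat) fragment, possibly repeatedly.
`simulate_periodic()` implements insertion-only dynamics -- each tract,
each day, suffers one insertion with probability `event_prob`, of length
drawn from `step_pmf` (default: point mass at 7; a triangular 5--9
alternative is provided for width studies). There is no periodic
contraction branch.

Estimation from a decomposition:

* `peak_intervals()` -- consecutive peak-mean differences in repeats.
  `interval_stats()` excludes intervals $\ge$ 12 repeats (the *doublet
  cutoff*: a missed intermediate peak makes two steps look like one
  14-repeat interval). Exclusion is the minimal reading of the cutoff;
  `halve_doublets = TRUE` instead re-admits each as two half-steps.
* `area_proportions()` -- peak areas rescaled so they sum to the sample's
  tract count (default 10,000), giving per-class tract counts. The
  insertion index $k$ is ordinal from the founder peak; a spacing-based
  mode `k = round((mu_k - mu_0)/(3 * modal step))` handles skipped
  classes, and the modal step is estimated after reducing each spacing by
  its integer multiplicity so that a skipped class does not bias it.
* `nonexpanding_fraction()` -- the founder class share (the first peak);
  `total_insertions()` -- $\sum_k k \cdot \mathrm{counts}_k$.
* `periodic_event_rate()` -- insertions per tract per day. The quoted
  0.018 corresponds to 10,000 insertions over 4,500 *expanding* tracts
  and 126 days; since the denominator convention is not printed anywhere,
  both `expanding_tracts` (default) and `all_tracts` are first-class
  options and the cohort analysis reports both.

The founder peak is identified as the lowest-mean peak; when a same-mouse
3-week tail mean is available in a cohort analysis it serves as the
reference the founder peak must coincide with.

## Simulators

`simulate_unitary()`, `simulate_periodic()` and `simulate_combined()`
evolve integer tract populations day by day with per-tract independence;
`simulate_combined()` applies the unitary and periodic steps independently
each day (the liver-like mixed regime). All take an integer seed and are
bit-reproducible; degenerate parameter sets consume no random numbers, so
a combined run with one process zeroed equals the remaining process alone
under the same seed. `simulate_unitary_poisson()` is a continuous-time
cross-check (Poisson event counts over the whole interval) that agrees in
distribution for small daily probabilities. Day-granularity Bernoulli
steps rather than Poisson are the primary dynamics because the model is
specified per day.

`simulate_pcr()` is a branching process for error-prone PCR from few
template molecules: each cycle every molecule duplicates with probability
`dup_prob` and each daughter slips by $\pm 1$ repeat with probability
`slip_prob` (sign equiprobable by default). Molecule counts are capped
(default 200,000) by uniform subsampling with the scale factor recorded,
or a resource error if subsampling is disabled. For `dup_prob = 1` the
final length distribution has a closed form by enumeration over the
number of daughter steps in a lineage; the tests compare against it at
small cycle counts.

`peak_resolvability()` quantifies the contrast between pure periodic and
unitary-contaminated populations: the fraction of adjacent fitted peak
pairs separated by more than twice the pooled (area-weighted RMS)
component $\sigma$. At the 20,000-cell scale a pure 7-repeat periodic
population decomposes with resolvability ~1, while adding tail-level
unitary dynamics ($p_e = 0.026$, $p_c = 0.010$) smears the ladder into
broad overlapping components and the metric collapses to ~0.

## The synthetic cohort generator

No raw traces are publicly deposited, so validation runs against
`render_trace()` / `generate_cohort()`, a forward model of the
measurement process that the fitting inverts:

* Each tract of length $L$ contributes a unit-area Gaussian kernel at
  $86 + 3L$ bp with standard deviation $3\,\sigma(L)$ bp, where
  $\sigma(L) = c_0 + c_1 L$ repeats is the PCR broadening model.
* The measured 3-week tail spread (1.98 repeats at 119 repeats) is
  attributed entirely to PCR/measurement broadening (founder biological
  spread zero). This is the only attribution consistent with treating
  $\Delta\sigma^2$ as purely biological in the drift inversion. The
  length dependence is a mild positive slope, $c_1 = 0.005$ per repeat,
  with $c_0$ solved so that $\sigma(119) = 1.98$.
* Longer tracts amplify less efficiently: kernel weights decay by a
  factor `attenuation` (default 0.995) per extra repeat, normalised so
  the rendered area equals the tract count. No quantitative attenuation
  is published; 0.995 expresses "reduced efficiency" without dominating
  the signal. Validation runs that are compared against printed numbers
  set it to 1, since those numbers were derived without an attenuation
  correction; runs probing the direction of the bias vary it.
* Additive Gaussian intensity noise (clipped at zero) is available but
  defaults to 0: the analysis targets are statistics of fitted peaks, and
  the package treats baseline/noise handling as upstream preprocessing.
  The default grid step is 0.5 bp; exported trace sampling density is not
  documented anywhere, so this is a declared choice, not a cited value.
* Default cohort dynamics: tail/peripheral tissues unitary with
  (0.026, 0.010); striatum periodic at 0.018/day with 45% of tracts
  expanding; cortex the same with 20%; liver a combined regime with a
  broad (uniform 3--12 repeat) insertion-length spread, which is a
  modelling choice to produce its weakly periodic bimodality, not an
  estimate. Ages default to 3/10/21 weeks with the 3-week sample as the
  unevolved founder reference; samples default to 10,000 tracts.

What the generator does *not* emulate: stutter minus-A artefacts, dye
pull-up, instrument saturation, inter-mouse founder variation, lineage
structure among cells. Passing tests therefore demonstrate that the
estimators invert the stated forward model at realistic scales, not that
they are robust to every instrument artefact of real capillary data.

`mix_populations()` and `small_pool_subsample()` reproduce the two
classical controls: mixed-ratio samples (area-ratio recovery with unit
slope across 1:9 to 9:1) and serial-dilution small pools (few-molecule
samples collapse onto the occupied length classes).

## Numerical and design choices

* Nelder--Mead per-component tolerance $10^{-12}$ (relative), 2000
  iterations, 3 jittered restarts; LM refinement to machine tolerance,
  500 iterations, quality-gated on the residual sum of squares against
  its starting point.
* Residual-argmax ties break toward lower bp; determinism throughout
  under fixed seeds (the package restores the caller's RNG state).
* `min_area_fraction` = 1% is the small-peak rejection rule; nothing is
  published about one, and 1% sits below every class the estimators rely
  on at the 10,000-tract scale.
* Degenerate inputs: zero-area traces, flat traces, empty populations,
  all-excluded interval sets and variance changes smaller than the drift
  implies all raise classed errors (`cagdyn_fit_error`,
  `cagdyn_estimation_error`, `cagdyn_resource_error`).
* Validation scales: the simulation-backed checks use 59 mice x 10,000
  tracts for the tail cohort, 30 samples for interval recovery, 20
  samples for the area estimators, and 100,000 tracts for moment
  checks -- the study's own sample sizes, kept to what a laptop runs in
  seconds.

## Known limitations

* The drift inversion uses the first-order variance equation; for
  parameter regimes far from the estimated ones ($|p_e - p_c|$ not small)
  the neglected $(p_e - p_c)^2 t$ term matters, and `estimate_drift()`
  applied to simulator output recovers parameters only up to that
  documented bias.
* Single-Gaussian fits of a skewed random-walk distribution track the
  mode slightly below the mean, so fitted cohort medians sit a few
  hundredths of a repeat below the analytic drift; the tolerance of the
  cohort checks absorbs this.
* Ordinal insertion indexing undercounts when an intermediate class is
  genuinely unoccupied; the spacing mode handles ladders with skipped
  classes but relies on a stable modal step.
* The liver regime is generated and fitted but has no dedicated
  estimator, mirroring the state of the analysis it reimplements.
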