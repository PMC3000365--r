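#' Trace rendering configuration
#'
#' Forward model of the measurement process that peak fitting inverts. Each
#' tract of L repeats contributes a unit-area Gaussian kernel centred at
#' `86 + 3 L` bp whose standard deviation is `3 * sigma(L)` bp, with the
#' PCR-broadening model `sigma(L) = c0 + c1 * L` in repeat units. Longer
#' tracts amplify less efficiently: each tract's kernel is weighted by
#' `attenuation^L` (weights normalised so the total area equals the tract
#' count). Additive Gaussian intensity noise, clipped at zero, completes the
#' model.
#'
#' Defaults: `c1 = 0.005` per repeat with `c0` solved so that
#' `sigma(119) = 1.98` repeats (the 3-week tail broadening), mild
#' attenuation `0.995` per extra repeat, no noise, and a 0.5 bp grid.
#'
#' @param pcr_sigma_c0,pcr_sigma_c1 Affine broadening model coefficients
#'   (repeats, repeats per repeat).
#' @param attenuation Relative amplification weight decay per extra repeat,
#'   in `(0, 1]`.
#' @param noise_sd Additive intensity noise standard deviation (intensity
#'   units; one tract has unit area).
#' @param grid_step Grid spacing, bp.
#' @param pad_sigmas Grid padding beyond the outermost kernels, in kernel
#'   sigmas.
#' @return An object of class `"trace_render_config"`.
#' @export
trace_render_config <- function(pcr_sigma_c0 = 1.98 - 0.005 * 119,
                                pcr_sigma_c1 = 0.005,
                                attenuation = 0.995,
                                noise_sd = 0,
                                grid_step = 0.5,
                                pad_sigmas = 5) {
  if (attenuation <= 0 || attenuation > 1)
    stop("attenuation must be in (0, 1]")
  if (grid_step <= 0) stop("grid_step must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(list(pcr_sigma_c0 = pcr_sigma_c0, pcr_sigma_c1 = pcr_sigma_c1,
                 attenuation = attenuation, noise_sd = noise_sd,
                 grid_step = grid_step, pad_sigmas = pad_sigmas),
            class = "trace_render_config")
}

pcr_sigma <- function(cfg, L) {
  s <- cfg$pcr_sigma_c0 + cfg$pcr_sigma_c1 * L
  if (any(s <= 0)) stop("sigma(L) must be positive over the support")
  s
}

#' Render a tract population as a fragment-analysis trace
#'
#' @param pop A [tract_population()].
#' @param cfg A [trace_render_config()].
#' @param seed Optional integer seed (used only for the additive noise).
#' @param mouse,tissue,age_weeks Metadata attached to the trace.
#' @return A [cag_trace()].
#' @examples
#' pop <- tract_population(119, 1000)
#' tr <- render_trace(pop, trace_render_config(attenuation = 1))
#' @export
render_trace <- function(pop, cfg = trace_render_config(), seed = NULL,
                         mouse = NA_character_, tissue = "other",
                         age_weeks = NA_real_) {
  stopifnot(inherits(pop, "tract_population"),
            inherits(cfg, "trace_render_config"))
  if (pop$n_tracts < 1L) stop("empty population")
  tab <- table(pop$repeats)
  L <- as.integer(names(tab))
  n_L <- as.numeric(tab)
  sig_bp <- BP_PER_REPEAT * pcr_sigma(cfg, L)
  centre_bp <- size_from_repeats(L)
  w <- n_L * cfg$attenuation^L
  w <- w * pop$n_tracts / sum(w)   # total rendered area = n_tracts
  lo <- min(centre_bp - cfg$pad_sigmas * sig_bp)
  hi <- max(centre_bp + cfg$pad_sigmas * sig_bp)
  grid <- seq(lo, hi, by = cfg$grid_step)
  intensity <- numeric(length(grid))
  for (i in seq_along(L))
    intensity <- intensity +
      w[[i]] * stats::dnorm(grid, centre_bp[[i]], sig_bp[[i]])
  if (cfg$noise_sd > 0) {
    with_seed(seed, {
      intensity <- intensity +
        stats::rnorm(length(grid), 0, cfg$noise_sd)
    })
    intensity[intensity < 0] <- 0
  }
  cag_trace(grid, intensity, mouse = mouse, tissue = tissue,
            age_weeks = age_weeks)
}

#' Mix two tract populations at a given ratio
#'
#' Weighted concatenation preserving the total tract count of `a`: the first
#' `round(ratio * n)` tracts come from `a`, the rest from `b` (dilution-
#' series style mixing of two homogeneous samples).
#'
#' @param a,b [tract_population()]s.
#' @param ratio Fraction of the mixture drawn from `a`, in `[0, 1]`.
#' @return A [tract_population()] with `a$n_tracts` tracts.
#' @export
mix_populations <- function(a, b, ratio) {
  stopifnot(inherits(a, "tract_population"),
            inherits(b, "tract_population"))
  if (ratio < 0 || ratio > 1) stop("ratio must be in [0, 1]")
  n <- a$n_tracts
  na <- as.integer(round(ratio * n))
  nb <- n - na
  if (nb > b$n_tracts) stop("population b too small for the requested mix")
  tract_population(c(a$repeats[seq_len(na)], b$repeats[seq_len(nb)]), n,
                   c(a$event_counts[seq_len(na)],
                     b$event_counts[seq_len(nb)]))
}

#' Small-pool subsample of a population
#'
#' Uniform sampling without replacement of `k` tracts, emulating the few
#' template molecules amplified after serial dilution.
#'
#' @param pop A [tract_population()].
#' @param k Number of tracts to keep, `1 <= k <= n_tracts`.
#' @param seed Optional integer seed.
#' @return A [tract_population()] of `k` tracts.
#' @export
small_pool_subsample <- function(pop, k, seed = NULL) {
  stopifnot(inherits(pop, "tract_population"))
  if (k < 1 || k > pop$n_tracts) stop("k out of range")
  idx <- with_seed(seed, sample.int(pop$n_tracts, k))
  tract_population(pop$repeats[idx], k, pop$event_counts[idx])
}

#' Cohort generation configuration
#'
#' Study-design defaults mirror the experimental layout the analysis is
#' meant for: a ~119-repeat founder tract, samples of ~10,000 tracts, ages
#' 3, 10 and 21 weeks, tail-like unitary drift in peripheral tissues,
#' periodic 7-repeat insertion in striatum (45\% of tracts expanding) and
#' cortex (20\%), and a mixed liver regime with a broad insertion-length
#' spread.
#'
#' @param n_mice Number of mice.
#' @param founder_repeats Founder CAG count shared by all tracts at 3 weeks.
#' @param tissues Named list of per-tissue dynamics. Each element is a list
#'   with `type` (`"unitary"`, `"periodic"` or `"combined"`) and the
#'   matching parameter objects: `drift` ([drift_params()]) and/or
#'   `periodic` ([periodic_params()]) plus, for periodic tissues,
#'   `expanding_fraction`.
#' @param ages_weeks Increasing sampling ages, weeks; the first age is the
#'   unevolved founder reference.
#' @param n_tracts Tracts per sample.
#' @param render A [trace_render_config()].
#' @param seed Integer seed for the whole cohort.
#' @return An object of class `"cohort_config"`.
#' @export
cohort_config <- function(n_mice = 10,
                          founder_repeats = 119,
                          tissues = default_tissue_dynamics(),
                          ages_weeks = c(3, 10, 21),
                          n_tracts = 10000,
                          render = trace_render_config(),
                          seed = 1) {
  if (is.unsorted(ages_weeks, strictly = TRUE))
    stop("ages_weeks must be increasing")
  for (nm in names(tissues)) {
    t <- tissues[[nm]]
    if (!is.list(t) || is.null(t$type) ||
        !t$type %in% c("unitary", "periodic", "combined"))
      stop("invalid tissue spec for ", nm)
    if (t$type %in% c("unitary", "combined") &&
        !inherits(t$drift, "drift_params"))
      stop("tissue ", nm, " needs drift_params")
    if (t$type %in% c("periodic", "combined") &&
        !inherits(t$periodic, "periodic_params"))
      stop("tissue ", nm, " needs periodic_params")
    ef <- t$expanding_fraction
    if (!is.null(ef) && (ef < 0 || ef > 1))
      stop("expanding_fraction must be in [0, 1]")
  }
  structure(list(n_mice = n_mice, founder_repeats = founder_repeats,
                 tissues = tissues, ages_weeks = ages_weeks,
                 n_tracts = n_tracts, render = render, seed = seed),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_tissue_dynamics <- function() {
  tail_drift <- drift_params(0.026, 0.010)
  list(
    tail = list(type = "unitary", drift = tail_drift),
    striatum = list(type = "periodic",
                    periodic = periodic_params(0.018),
                    expanding_fraction = 0.45),
    cortex = list(type = "periodic",
                  periodic = periodic_params(0.018),
                  expanding_fraction = 0.20),
    liver = list(type = "combined", drift = tail_drift,
                 periodic = periodic_params(
                   0.005,
                   stats::setNames(rep(1 / 10, 10), as.character(3:12))),
                 expanding_fraction = 1))
}

evolve_tissue <- function(pop, spec, days, seed) {
  ef <- if (is.null(spec$expanding_fraction)) 1 else spec$expanding_fraction
  n_exp <- as.integer(round(ef * pop$n_tracts))
  if (n_exp < pop$n_tracts && spec$type != "unitary") {
    # only the expanding subset evolves; the rest retain the founder length
    sub <- tract_population(pop$repeats[seq_len(n_exp)], n_exp,
                            pop$event_counts[seq_len(n_exp)])
    ev <- switch(spec$type,
      periodic = simulate_periodic(sub, spec$periodic, days, seed),
      combined = simulate_combined(sub, spec$drift, spec$periodic, days,
                                   seed))
    keep <- seq.int(n_exp + 1L, pop$n_tracts)
    tract_population(c(ev$repeats, pop$repeats[keep]), pop$n_tracts,
                     c(ev$event_counts, pop$event_counts[keep]))
  } else {
    switch(spec$type,
      unitary = simulate_unitary(pop, spec$drift, days, seed),
      periodic = simulate_periodic(pop, spec$periodic, days, seed),
      combined = simulate_combined(pop, spec$drift, spec$periodic, days,
                                   seed))
  }
}

#' Generate a full synthetic multi-tissue cohort
#'
#' For each mouse, every tract starts at the founder length. The
#' first-listed age is rendered directly from the founder population (the
#' tail-biopsy reference); each later age renders a population evolved by
#' the per-tissue dynamics over `(age - first age) * 7` days. For periodic
#' tissues only the configured expanding fraction of tracts evolves. Ground
#' truth populations are retained alongside every rendered trace.
#'
#' @param cfg A [cohort_config()].
#' @return An object of class `"cag_cohort"`: list with `samples` (each a
#'   list `trace`, `population`, `mouse`, `tissue`, `age_weeks`),
#'   a `manifest` data frame, and the resolved `config`.
#' @export
generate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "cohort_config"))
  samples <- list()
  ref_age <- cfg$ages_weeks[[1L]]
  counter <- 0L
  for (m in seq_len(cfg$n_mice)) {
    mouse <- sprintf("mouse%03d", m)
    founder <- tract_population(cfg$founder_repeats, cfg$n_tracts)
    for (tis in names(cfg$tissues)) {
      for (age in cfg$ages_weeks) {
        counter <- counter + 1L
        sub_seed <- (cfg$seed * 1000L + counter) %% .Machine$integer.max
        days <- round((age - ref_age) * 7)
        pop <- if (days == 0) founder
               else evolve_tissue(founder, cfg$tissues[[tis]], days,
                                  sub_seed)
        tr <- render_trace(pop, cfg$render, seed = sub_seed + 1L,
                           mouse = mouse, tissue = tis, age_weeks = age)
        samples[[length(samples) + 1L]] <-
          list(trace = tr, population = pop, mouse = mouse, tissue = tis,
               age_weeks = age)
      }
    }
  }
  manifest <- data.frame(
    mouse = vapply(samples, `[[`, character(1), "mouse"),
    tissue = vapply(samples, `[[`, character(1), "tissue"),
    age_weeks = vapply(samples, `[[`, numeric(1), "age_weeks"))
  structure(list(samples = samples, manifest = manifest, config = cfg),
            class = "cag_cohort")
}

#' @export
print.cag_cohort <- function(x, ...) {
  cat(sprintf("<cag_cohort> %d samples (%d mice x %d tissue(s) x %d age(s))\n",
              nrow(x$manifest), x$config$n_mice, length(x$config$tissues),
              length(x$config$ages_weeks)))
  print(utils::head(x$manifest))
  invisible(x)
}

#' Write a cohort to disk as traces, populations and a manifest
#'
#' Lays out one trace file and one ground-truth population file per sample
#' under `dir`, plus `manifest.tsv` linking them and `config.txt` echoing
#' the resolved configuration (including the seed).
#'
#' @param cohort A `"cag_cohort"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "cag_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  man <- cohort$manifest
  man$trace_file <- sprintf("%s_%s_%gwk.trace.tsv", man$mouse, man$tissue,
                            man$age_weeks)
  man$population_file <- sub("\\.trace\\.tsv$", ".pop.tsv", man$trace_file)
  for (i in seq_along(cohort$samples)) {
    s <- cohort$samples[[i]]
    write_trace(s$trace, file.path(dir, man$trace_file[[i]]))
    write_population(s$population, file.path(dir, man$population_file[[i]]))
  }
  utils::write.table(man, file.path(dir, "manifest.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg <- cohort$config
  write_keyvalue(list(n_mice = cfg$n_mice,
                      founder_repeats = cfg$founder_repeats,
                      ages_weeks = paste(cfg$ages_weeks, collapse = ","),
                      n_tracts = cfg$n_tracts,
                      tissues = paste(names(cfg$tissues), collapse = ","),
                      attenuation = cfg$render$attenuation,
                      noise_sd = cfg$render$noise_sd,
                      grid_step = cfg$render$grid_step,
                      seed = cfg$seed),
                 file.path(dir, "config.txt"))
  invisible(dir)
}

#' Striatum-style population with a fixed founder-retention fraction
#'
#' Draws per-tract insertion-event counts directly: a `nonexpanding`
#' fraction of tracts stays at the founder length (k = 0) and the rest
#' receive k >= 1 events from a zero-truncated Poisson whose mean is
#' `mean_events`, each event inserting `step` repeats. Useful when the
#' target of a simulation is a known per-sample insertion total rather than
#' a daily event rate.
#'
#' @param n_tracts Number of tracts.
#' @param founder_repeats Founder CAG count.
#' @param nonexpanding Fraction of tracts with zero events.
#' @param mean_events Mean event count among expanding tracts (> 1).
#' @param step Insertion length, repeats.
#' @param seed Optional integer seed.
#' @return A [tract_population()] with `event_counts` filled in.
#' @export
make_striatum_population <- function(n_tracts = 10000, founder_repeats = 119,
                                     nonexpanding = 0.54, mean_events = 2.2,
                                     step = 7, seed = NULL) {
  if (nonexpanding < 0 || nonexpanding > 1)
    stop("nonexpanding must be in [0, 1]")
  if (mean_events <= 1)
    stop("mean_events must exceed 1 for a zero-truncated Poisson")
  lambda <- stats::uniroot(
    function(l) l / (1 - exp(-l)) - mean_events,
    c(1e-8, 10 * mean_events))$root
  n0 <- as.integer(round(nonexpanding * n_tracts))
  n1 <- n_tracts - n0
  k <- with_seed(seed, {
    out <- integer(n1)
    todo <- seq_len(n1)
    while (length(todo)) {           # rejection-sample the zero class away
      draw <- stats::rpois(length(todo), lambda)
      out[todo] <- draw
      todo <- todo[draw == 0L]
    }
    out
  })
  tract_population(c(rep(founder_repeats, n0), founder_repeats + step * k),
                   n_tracts, c(integer(n0), k))
}
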