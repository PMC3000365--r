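test_that("render-fit round trip recovers a single length class", {
  cfg <- clean_render()
  pop <- tract_population(119, 5000)
  tr <- render_trace(pop, cfg)
  pk <- fit_single_gaussian(tr)
  expect_equal(pk$mean_bp, 86 + 3 * 119, tolerance = 0.05 / 443)
  expect_equal(pk$sigma_bp, 3 * 1.98, tolerance = 0.02)
  # rendered area equals the tract count
  expect_equal(trace_area(tr), 5000, tolerance = 0.01)
})

test_that("noiseless renders are decomposed essentially exactly", {
  cfg <- clean_render()
  pop <- tract_population(c(rep(119, 5000), rep(126, 3000), rep(133, 2000)))
  d <- decompose(render_trace(pop, cfg))
  expect_equal(d$n_peaks, 3L)
  expect_gte(d$explained_fraction, 0.999)
  expect_equal(unname(area_proportions(d)$counts), c(5000, 3000, 2000),
               tolerance = 0.02)
})

test_that("equal sub-populations fit with unit area ratio", {
  cfg <- clean_render()
  pop <- tract_population(c(rep(119, 5000), rep(126, 5000)))
  d <- decompose(render_trace(pop, cfg))
  expect_equal(d$n_peaks, 2L)
  expect_equal(d$peaks$area[[1]] / d$peaks$area[[2]], 1, tolerance = 0.02)
})

test_that("amplification attenuation biases long classes down, monotonically", {
  pop <- tract_population(c(rep(119, 5000), rep(126, 5000)))
  ratios <- sapply(c(1, 0.995, 0.98), function(a) {
    d <- decompose(render_trace(pop, trace_render_config(attenuation = a)))
    d$peaks$area[[2]] / d$peaks$area[[1]]
  })
  expect_equal(ratios[[1]], 1, tolerance = 0.02)
  # closed form: the weight ratio of classes 7 repeats apart is a^7
  expect_equal(ratios[[2]], 0.995^7, tolerance = 0.01)
  expect_equal(ratios[[3]], 0.98^7, tolerance = 0.01)
  expect_true(all(diff(ratios) < 0))
})

test_that("additive noise is seeded and clipped at zero", {
  cfg <- trace_render_config(attenuation = 1, noise_sd = 5)
  pop <- tract_population(119, 1000)
  t1 <- render_trace(pop, cfg, seed = 21)
  t2 <- render_trace(pop, cfg, seed = 21)
  t3 <- render_trace(pop, cfg, seed = 22)
  expect_identical(t1$intensity, t2$intensity)
  expect_false(identical(t1$intensity, t3$intensity))
  expect_true(all(t1$intensity >= 0))
})

test_that("population mixing recovers the mixed proportion with slope one", {
  cfg <- clean_render()
  a <- tract_population(120, 10000)
  b <- tract_population(129, 10000)
  expect_identical(mix_populations(a, b, 0)$repeats, b$repeats)
  expect_identical(mix_populations(a, b, 1)$repeats, a$repeats)
  ratios <- seq(0.1, 0.9, by = 0.1)
  est <- sapply(ratios, function(r) {
    d <- decompose(render_trace(mix_populations(a, b, r), cfg))
    unname(area_proportions(d)$counts[[1]]) / 10000
  })
  expect_lt(max(abs(est - ratios)), 0.05)
  slope <- unname(coef(lm(est ~ ratios))[[2]])
  expect_equal(slope, 1, tolerance = 0.05)
})

test_that("small-pool subsampling mimics serial dilution", {
  pop <- make_striatum_population(2000, nonexpanding = 0.4, seed = 3)
  all_of_it <- small_pool_subsample(pop, 2000, seed = 4)
  expect_equal(sort(all_of_it$repeats), sort(pop$repeats))

  one <- small_pool_subsample(pop, 1, seed = 4)
  d1 <- decompose(render_trace(one, clean_render()))
  expect_equal(d1$n_peaks, 1L)
  expect_true(round(d1$peaks$mean_repeats) %in% unique(pop$repeats))

  # k = 10 draws concentrate on the occupied length classes
  occupied <- 86 + 3 * sort(unique(pop$repeats))
  for (s in 1:5) {
    sub <- small_pool_subsample(pop, 10, seed = s)
    d <- suppressWarnings(decompose(render_trace(sub, clean_render())))
    nearest <- sapply(d$peaks$mean_bp, function(m) min(abs(m - occupied)))
    expect_lt(max(nearest) / 3, 1)  # within 1 repeat of a true class
  }
  expect_error(small_pool_subsample(pop, 0), "out of range")
  expect_error(small_pool_subsample(pop, 2001), "out of range")
})

test_that("null-dynamics cohorts stay at the founder length at all ages", {
  cfg <- cohort_config(
    n_mice = 2, n_tracts = 2000,
    tissues = list(tail = list(type = "unitary",
                               drift = drift_params(0, 0))),
    render = clean_render(), seed = 2)
  co <- generate_cohort(cfg)
  for (s in co$samples) {
    pk <- fit_single_gaussian(s$trace)
    expect_equal(pk$mean_bp, 443, tolerance = 0.1 / 443)
  }
})

test_that("generated cohorts are identifiable end to end", {
  # one striatum-like tissue with known expanding fraction and step
  cfg <- cohort_config(
    n_mice = 3, n_tracts = 10000,
    tissues = list(striatum = list(type = "periodic",
                                   periodic = periodic_params(0.018),
                                   expanding_fraction = 0.45)),
    ages_weeks = c(3, 21), render = clean_render(), seed = 6)
  co <- generate_cohort(cfg)
  old <- co$samples[vapply(co$samples, `[[`, numeric(1), "age_weeks") == 21]
  nonexp <- steps <- numeric(0)
  for (s in old) {
    d <- suppressWarnings(decompose(s$trace))
    pr <- suppressWarnings(area_proportions(d))
    nonexp <- c(nonexp, nonexpanding_fraction(pr))
    steps <- c(steps, peak_intervals(d)$intervals)
  }
  # tracts in the expanding subset that saw zero events by 21 weeks also
  # sit in the founder peak: P(Binom(126, 0.018) = 0) ~ 0.10
  expected_nonexp <- 0.55 + 0.45 * dbinom(0, 126, 0.018)
  expect_equal(mean(nonexp), expected_nonexp, tolerance = 0.05)
  expect_equal(median(round(steps)), 7)

  # and a tail tissue recovers its drift parameters
  cfg2 <- cohort_config(
    n_mice = 6, n_tracts = 10000,
    tissues = list(tail = list(type = "unitary",
                               drift = drift_params(0.026, 0.010))),
    ages_weeks = c(3, 20), render = clean_render(), seed = 7)
  co2 <- generate_cohort(cfg2)
  moments <- list()
  for (m in unique(co2$manifest$mouse)) {
    idx <- which(co2$manifest$mouse == m)
    fits <- lapply(co2$samples[idx], function(s) fit_single_gaussian(s$trace))
    ages <- co2$manifest$age_weeks[idx]
    f3 <- fits[[which(ages == 3)]]; f20 <- fits[[which(ages == 20)]]
    moments[[m]] <- drift_observation(
      repeats_from_size(f3$mean_bp), repeats_from_size(f20$mean_bp),
      f3$sigma_bp / 3, f20$sigma_bp / 3, 119)
  }
  # founder mu is a point mass, so the sigma-on-mu trend is degenerate
  pm <- suppressWarnings(cohort_summary(moments))$per_mouse
  est <- estimate_drift(drift_observation(
    mean(pm$mu_start), mean(pm$mu_end),
    mean(pm$sigma_start), mean(pm$sigma_end), 119))
  # allowance: 3 MC standard errors plus the documented second-order
  # variance-term bias of the drift equations
  n_eff <- 6 * 10000
  se <- sqrt(exact_step_variance(drift_params(0.026, 0.010)) / 119 / n_eff)
  bias <- (0.026 - 0.010)^2 / 2
  expect_lt(abs(est$p_e - 0.026), 3 * se + bias + 0.001)
  expect_lt(abs(est$p_c - 0.010), 3 * se + bias + 0.001)
})

test_that("cohort configuration rejects invalid tissue specs", {
  expect_error(cohort_config(tissues = list(tail = list(type = "odd"))),
               "invalid tissue spec")
  expect_error(cohort_config(tissues = list(tail = list(type = "unitary"))),
               "needs drift_params")
  expect_error(cohort_config(ages_weeks = c(21, 3)), "increasing")
  expect_error(
    cohort_config(tissues = list(striatum = list(
      type = "periodic", periodic = periodic_params(0.01),
      expanding_fraction = 1.4))),
    "expanding_fraction")
})

test_that("cohorts serialise to traces, populations, manifest and config", {
  cfg <- cohort_config(n_mice = 1, n_tracts = 500,
                       tissues = default_tissue_dynamics()["tail"],
                       ages_weeks = c(3, 21), render = clean_render(),
                       seed = 3)
  dir <- withr::local_tempdir()
  co <- generate_cohort(cfg)
  write_cohort(co, dir)
  man <- read.table(file.path(dir, "manifest.tsv"), header = TRUE,
                    sep = "\t")
  expect_equal(nrow(man), 2L)
  tr <- read_trace(file.path(dir, man$trace_file[[1]]))
  expect_s3_class(tr, "cag_trace")
  expect_identical(tr$meta$tissue, "tail")
  pop <- read_population(file.path(dir, man$population_file[[1]]))
  expect_equal(pop$n_tracts, 500L)
  cfg_txt <- readLines(file.path(dir, "config.txt"))
  expect_true(any(grepl("^seed\t3", cfg_txt)))
})

test_that("striatum population generator hits its target moments", {
  pop <- make_striatum_population(20000, nonexpanding = 0.54,
                                  mean_events = 2.2, seed = 5)
  expect_equal(mean(pop$event_counts == 0), 0.54, tolerance = 0.01)
  k <- pop$event_counts[pop$event_counts > 0]
  expect_equal(mean(k), 2.2, tolerance = 0.05)
  expect_true(all((pop$repeats - 119) == 7 * pop$event_counts))
})
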