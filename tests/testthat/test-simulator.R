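test_that("identical seeds give bit-identical populations", {
  pop <- tract_population(119, 2000)
  p <- drift_params(0.026, 0.010)
  expect_population_equal(simulate_unitary(pop, p, 30, seed = 9),
                          simulate_unitary(pop, p, 30, seed = 9))
  pp <- periodic_params(0.02)
  expect_population_equal(simulate_periodic(pop, pp, 30, seed = 9),
                          simulate_periodic(pop, pp, 30, seed = 9))
  r1 <- simulate_pcr(tract_population(119, 3), 10, 0.1, 0.8, seed = 9)
  r2 <- simulate_pcr(tract_population(119, 3), 10, 0.1, 0.8, seed = 9)
  expect_identical(r1$lengths, r2$lengths)
})

test_that("degenerate dynamics leave the population unchanged", {
  pop <- tract_population(c(100, 119, 140))
  out <- simulate_unitary(pop, drift_params(0, 0), 50, seed = 1)
  expect_identical(out$repeats, pop$repeats)
  out2 <- simulate_periodic(pop, periodic_params(0), 50, seed = 1)
  expect_identical(out2$repeats, pop$repeats)
  expect_identical(out2$event_counts, integer(3))
})

test_that("unitary moments match the closed-form drift and variance", {
  n <- 1e5
  p <- drift_params(0.026, 0.010)
  days <- 119
  out <- simulate_unitary(tract_population(119, n), p, days, seed = 42)
  exp_mu <- (p$p_e - p$p_c) * days
  exp_var <- exact_step_variance(p) * days
  se_mu <- sqrt(exp_var / n)
  se_var <- exp_var * sqrt(2 / (n - 1))
  expect_lt(abs(mean(out$repeats) - 119 - exp_mu), 3 * se_mu)
  expect_lt(abs(var(out$repeats) - exp_var), 3 * se_var)
})

test_that("pure birth dynamics are monotone with the expected shift", {
  pop <- tract_population(119, 20000)
  out <- simulate_unitary(pop, drift_params(0.5, 0), 10, seed = 3)
  expect_true(all(out$repeats >= 119))
  expect_equal(mean(out$repeats) - 119, 5, tolerance = 0.02)
})

test_that("periodic insertion lengths are multiples of the step", {
  pop <- tract_population(119, 5000)
  out <- simulate_periodic(pop, periodic_params(0.05), 40, seed = 5)
  gain <- out$repeats - 119
  expect_true(all(gain %% 7 == 0))
  expect_equal(gain, 7 * out$event_counts)
})

test_that("periodic event counts are Binomial(days, event_prob)", {
  n <- 1e5
  out <- simulate_periodic(tract_population(119, n), periodic_params(0.05),
                           20, seed = 43)
  lv <- 0:10
  obs <- as.numeric(table(factor(out$event_counts, levels = lv)))
  expd <- dbinom(lv, 20, 0.05) * n
  keep <- expd > 5
  chi <- sum((obs[keep] - expd[keep])^2 / expd[keep])
  expect_gt(pchisq(chi, sum(keep) - 1, lower.tail = FALSE), 0.01)
})

test_that("combined dynamics degenerate to their constituents", {
  pop <- tract_population(119, 3000)
  pp <- periodic_params(0.02)
  dp <- drift_params(0.026, 0.010)
  expect_population_equal(
    simulate_combined(pop, drift_params(0, 0), pp, 40, seed = 7),
    simulate_periodic(pop, pp, 40, seed = 7))
  expect_population_equal(
    simulate_combined(pop, dp, periodic_params(0), 40, seed = 7),
    simulate_unitary(pop, dp, 40, seed = 7))
})

test_that("the step pmf is validated and the triangular spread works", {
  expect_error(periodic_params(1.5), "event_prob")
  expect_error(periodic_params(0.1, c("7" = 0.5)), "summing to 1")
  expect_error(periodic_params(0.1, c("0" = 1)), "positive integer")
  pmf <- step_pmf_triangular()
  expect_equal(sum(pmf), 1)
  out <- simulate_periodic(tract_population(119, 5000),
                           periodic_params(0.5, pmf), 2, seed = 8)
  steps <- (out$repeats - 119)[out$event_counts == 1]
  expect_true(all(steps >= 5 & steps <= 9))
})

test_that("error-free PCR conserves the template length distribution", {
  tp <- tract_population(c(rep(119, 5), rep(125, 5)))
  r <- simulate_pcr(tp, cycles = 8, slip_prob = 0, dup_prob = 0.7, seed = 3)
  expect_setequal(unique(r$lengths), c(119, 125))
  # relative class frequencies stay at the template ratio in expectation;
  # exactly so for dup_prob = 1
  r2 <- simulate_pcr(tp, cycles = 5, slip_prob = 0, dup_prob = 1, seed = 3)
  expect_equal(mean(r2$lengths == 119), 0.5)
  expect_equal(r2$n_molecules, 10 * 2^5)
})

test_that("one perfect cycle of fully error-prone PCR is exhaustive", {
  r <- simulate_pcr(tract_population(119, 1), cycles = 1, slip_prob = 1,
                    dup_prob = 1, seed = 4)
  expect_equal(r$n_molecules, 2L)
  expect_true(119 %in% r$lengths)
  expect_true(any(r$lengths %in% c(118, 120)))
})

test_that("PCR length distribution matches brute-force enumeration", {
  # dup_prob = 1: after c cycles a uniformly chosen molecule has j slip
  # opportunities with weight choose(c, j)/2^c; each opportunity slips with
  # probability s, sign equiprobable -> exact pmf by enumeration
  cyc <- 6; s <- 0.2; t0 <- 119
  pmf <- stats::setNames(numeric(2 * cyc + 1), (t0 - cyc):(t0 + cyc))
  for (j in 0:cyc) {
    w <- choose(cyc, j) / 2^cyc
    for (k in 0:j) {
      pk <- dbinom(k, j, s)
      for (up in 0:k) {
        len <- as.character(t0 + up - (k - up))
        pmf[len] <- pmf[len] + w * pk * dbinom(up, k, 0.5)
      }
    }
  }
  n0 <- 3000
  r <- simulate_pcr(tract_population(t0, n0), cycles = cyc, slip_prob = s,
                    dup_prob = 1, max_molecules = n0 * 2^cyc, seed = 5)
  emp <- table(factor(r$lengths, levels = names(pmf))) / length(r$lengths)
  expect_lt(max(abs(as.numeric(emp) - pmf)), 0.005)
})

test_that("the molecule cap subsamples uniformly or errors out", {
  r <- simulate_pcr(tract_population(119, 1), cycles = 20, slip_prob = 0.01,
                    dup_prob = 1, max_molecules = 5000, seed = 6)
  expect_equal(r$n_molecules, 5000L)
  expect_gt(r$scale, 1)
  expect_error(
    simulate_pcr(tract_population(119, 1), cycles = 20, slip_prob = 0.01,
                 dup_prob = 1, max_molecules = 5000, subsample = FALSE,
                 seed = 6),
    class = "cagdyn_resource_error")
})

test_that("Poisson thinning agrees with the daily walk in its moments", {
  n <- 5e4
  p <- drift_params(0.026, 0.010)
  a <- simulate_unitary(tract_population(119, n), p, 119, seed = 12)
  b <- simulate_unitary_poisson(tract_population(119, n), p, 119, seed = 12)
  se <- sqrt(2 * exact_step_variance(p) * 119 / n)
  expect_lt(abs(mean(a$repeats) - mean(b$repeats)), 3 * se)
  expect_lt(abs(var(a$repeats) - var(b$repeats)),
            3 * exact_step_variance(p) * 119 * sqrt(2 / n) * 2)
})

test_that("population snapshots round-trip with their config header", {
  pop <- simulate_periodic(tract_population(119, 200), periodic_params(0.1),
                           10, seed = 2)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_population(pop, path, config = list(seed = 2, days = 10))
  back <- read_population(path)
  expect_population_equal(pop, back)
  expect_match(readLines(path, n = 1), "^# seed")
})
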