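#' A population of CAG repeat tracts
#'
#' The simulators' state: one integer repeat count per tract, plus a
#' per-tract tally of periodic insertion events.
#'
#' @param repeats Integer repeat counts (>= 0), one per tract; a single
#'   value is recycled to `n_tracts`.
#' @param n_tracts Number of tracts when `repeats` is scalar.
#' @param event_counts Per-tract periodic event tallies (default all zero).
#' @return An object of class `"tract_population"`.
#' @examples
#' tract_population(119, n_tracts = 10000)
#' @export
tract_population <- function(repeats, n_tracts = length(repeats),
                             event_counts = NULL) {
  if (length(repeats) == 1L) repeats <- rep(repeats, n_tracts)
  repeats <- as.integer(round(repeats))
  if (any(repeats < 0)) stop("repeat counts must be non-negative")
  if (length(repeats) != n_tracts)
    stop("n_tracts inconsistent with length(repeats)")
  if (is.null(event_counts)) event_counts <- integer(n_tracts)
  event_counts <- as.integer(event_counts)
  if (length(event_counts) != n_tracts || any(event_counts < 0))
    stop("event_counts must be non-negative, one per tract")
  structure(list(repeats = repeats, n_tracts = n_tracts,
                 event_counts = event_counts),
            class = "tract_population")
}

#' @export
print.tract_population <- function(x, ...) {
  cat(sprintf(
    "<tract_population> %d tracts, repeats %d-%d (mean %.2f, sd %.2f)\n",
    x$n_tracts, min(x$repeats), max(x$repeats), mean(x$repeats),
    stats::sd(x$repeats)))
  invisible(x)
}

#' Periodic insertion parameters
#'
#' @param event_prob Probability that a tract suffers one insertion event on
#'   a given day, in `[0, 1]`.
#' @param step_pmf Probability mass over insertion lengths in repeats: a
#'   numeric vector named by positive-integer lengths, summing to 1. The
#'   default is a point mass at 7 repeats; [step_pmf_triangular()] gives a
#'   5-9 repeat spread.
#' @return An object of class `"periodic_params"`.
#' @export
periodic_params <- function(event_prob, step_pmf = c("7" = 1)) {
  if (event_prob < 0 || event_prob > 1)
    stop("event_prob must be in [0, 1]")
  lens <- suppressWarnings(as.integer(names(step_pmf)))
  if (anyNA(lens) || any(lens <= 0))
    stop("step_pmf must be named by positive integer repeat lengths")
  if (any(step_pmf < 0) || abs(sum(step_pmf) - 1) > 1e-9)
    stop("step_pmf must be a probability mass function summing to 1")
  structure(list(event_prob = event_prob,
                 step_pmf = stats::setNames(as.numeric(step_pmf),
                                            names(step_pmf))),
            class = "periodic_params")
}

#' @rdname periodic_params
#' @export
step_pmf_triangular <- function() {
  stats::setNames(c(1, 2, 3, 2, 1) / 9, as.character(5:9))
}

#' @export
print.periodic_params <- function(x, ...) {
  cat(sprintf("<periodic_params> event_prob = %.4g/day, steps {%s}\n",
              x$event_prob,
              paste(sprintf("%s:%.3g", names(x$step_pmf), x$step_pmf),
                    collapse = ", ")))
  invisible(x)
}

#' Simulate the daily unitary expansion/contraction walk
#'
#' Each tract, each day, independently gains one repeat with probability
#' `p_e`, loses one with probability `p_c`, and is otherwise unchanged; the
#' outcomes are mutually exclusive within a day. Repeat counts are floored
#' at zero. With a fixed seed the result is bit-identical across runs.
#'
#' @param pop A [tract_population()].
#' @param params A [drift_params()].
#' @param days Integer number of days (>= 0).
#' @param seed Optional integer seed.
#' @return The evolved [tract_population()].
#' @examples
#' p <- simulate_unitary(tract_population(119, 1000),
#'                       drift_params(0.026, 0.010), 119, seed = 1)
#' @export
simulate_unitary <- function(pop, params, days, seed = NULL) {
  stopifnot(inherits(pop, "tract_population"),
            inherits(params, "drift_params"))
  if (days < 0) stop("days must be non-negative")
  days <- as.integer(days)
  rep_ <- pop$repeats
  with_seed(seed, {
    for (d in seq_len(days)) {
      u <- stats::runif(pop$n_tracts)
      rep_ <- rep_ + (u < params$p_e) -
        (u >= params$p_e & u < params$p_e + params$p_c)
      rep_[rep_ < 0L] <- 0L
    }
  })
  tract_population(rep_, pop$n_tracts, pop$event_counts)
}

#' Simulate periodic stepwise insertion
#'
#' Each tract, each day, suffers one insertion event with probability
#' `event_prob`; the inserted length (in repeats) is drawn from `step_pmf`.
#' There is no periodic contraction branch. Event tallies are accumulated in
#' `event_counts`.
#'
#' @param pop A [tract_population()].
#' @param params A [periodic_params()].
#' @param days Integer number of days (>= 0).
#' @param seed Optional integer seed.
#' @return The evolved [tract_population()] with updated `event_counts`.
#' @export
simulate_periodic <- function(pop, params, days, seed = NULL) {
  stopifnot(inherits(pop, "tract_population"),
            inherits(params, "periodic_params"))
  if (days < 0) stop("days must be non-negative")
  days <- as.integer(days)
  rep_ <- pop$repeats
  ev <- pop$event_counts
  lens <- as.integer(names(params$step_pmf))
  with_seed(seed, {
    for (d in seq_len(days)) {
      hit <- stats::runif(pop$n_tracts) < params$event_prob
      nh <- sum(hit)
      if (nh) {
        steps <- if (length(lens) == 1L) rep(lens, nh)
                 else sample(lens, nh, replace = TRUE,
                             prob = params$step_pmf)
        rep_[hit] <- rep_[hit] + steps
        ev[hit] <- ev[hit] + 1L
      }
    }
  })
  tract_population(rep_, pop$n_tracts, ev)
}

#' Simulate combined unitary and periodic dynamics
#'
#' Per day, the unitary +/-1 step and the periodic insertion step are applied
#' independently to every tract (the liver-like mixed regime).
#'
#' @param pop A [tract_population()].
#' @param unitary A [drift_params()].
#' @param periodic A [periodic_params()].
#' @param days Integer number of days (>= 0).
#' @param seed Optional integer seed.
#' @return The evolved [tract_population()].
#' @export
simulate_combined <- function(pop, unitary, periodic, days, seed = NULL) {
  stopifnot(inherits(pop, "tract_population"),
            inherits(unitary, "drift_params"),
            inherits(periodic, "periodic_params"))
  if (days < 0) stop("days must be non-negative")
  days <- as.integer(days)
  rep_ <- pop$repeats
  ev <- pop$event_counts
  lens <- as.integer(names(periodic$step_pmf))
  # degenerate branches draw nothing, so a combined run with one process
  # zeroed consumes the same random stream as the remaining process alone
  with_seed(seed, {
    for (d in seq_len(days)) {
      if (unitary$p_e + unitary$p_c > 0) {
        u <- stats::runif(pop$n_tracts)
        rep_ <- rep_ + (u < unitary$p_e) -
          (u >= unitary$p_e & u < unitary$p_e + unitary$p_c)
      }
      if (periodic$event_prob > 0) {
        hit <- stats::runif(pop$n_tracts) < periodic$event_prob
        nh <- sum(hit)
        if (nh) {
          steps <- if (length(lens) == 1L) rep(lens, nh)
                   else sample(lens, nh, replace = TRUE,
                               prob = periodic$step_pmf)
          rep_[hit] <- rep_[hit] + steps
          ev[hit] <- ev[hit] + 1L
        }
      }
      rep_[rep_ < 0L] <- 0L
    }
  })
  tract_population(rep_, pop$n_tracts, ev)
}

#' Simulate error-prone PCR as a branching process
#'
#' Starting from template molecules, each cycle every molecule duplicates
#' with probability `dup_prob`; each daughter independently suffers a +/-1
#' repeat slippage with probability `slip_prob` (sign equiprobable unless
#' `expand_bias` is changed). When the molecule count would exceed
#' `max_molecules` the population is uniformly subsampled to that cap (if
#' `subsample = TRUE`; otherwise a resource error is raised) and the applied
#' scale factor is recorded.
#'
#' @param templates A [tract_population()] of template molecules.
#' @param cycles Number of PCR cycles (default 35).
#' @param slip_prob Probability a daughter strand slips by one repeat.
#' @param dup_prob Probability a molecule duplicates in a cycle.
#' @param expand_bias Probability that a slip is an expansion (+1) rather
#'   than a contraction; default 0.5.
#' @param max_molecules Cap on the simulated molecule count.
#' @param subsample Subsample uniformly at the cap instead of erroring.
#' @param seed Optional integer seed.
#' @return A list with `lengths` (integer repeat counts of the final,
#'   possibly subsampled, molecule multiset), `n_molecules` (represented
#'   count after capping) and `scale` (total molecules each retained
#'   molecule stands for; 1 when no subsampling occurred).
#' @export
simulate_pcr <- function(templates, cycles = 35, slip_prob, dup_prob,
                         expand_bias = 0.5, max_molecules = 200000,
                         subsample = TRUE, seed = NULL) {
  stopifnot(inherits(templates, "tract_population"))
  if (cycles < 1) stop("cycles must be >= 1")
  if (slip_prob < 0 || slip_prob > 1 || dup_prob < 0 || dup_prob > 1)
    stop("probabilities must be in [0, 1]")
  lens <- templates$repeats
  scale <- 1
  with_seed(seed, {
    for (cy in seq_len(cycles)) {
      n <- length(lens)
      dup <- stats::runif(n) < dup_prob
      daughters <- lens[dup]
      nd <- length(daughters)
      if (nd) {
        slips <- stats::runif(nd) < slip_prob
        ns <- sum(slips)
        if (ns) {
          sign <- ifelse(stats::runif(ns) < expand_bias, 1L, -1L)
          daughters[slips] <- pmax(daughters[slips] + sign, 0L)
        }
      }
      lens <- c(lens, daughters)
      if (length(lens) > max_molecules) {
        if (!subsample)
          stop(errorCondition(
            sprintf("molecule count %d exceeds cap %d", length(lens),
                    max_molecules),
            class = c("cagdyn_resource_error", "error", "condition")))
        scale <- scale * length(lens) / max_molecules
        lens <- lens[sample.int(length(lens), max_molecules)]
      }
    }
  })
  list(lengths = as.integer(lens), n_molecules = length(lens),
       scale = scale)
}

#' Poisson-thinned variant of the unitary walk
#'
#' Continuous-time check on the daily Bernoulli discretisation: event counts
#' over the whole interval are drawn as Poisson with rates `p_e * days` and
#' `p_c * days` per tract. Agrees with [simulate_unitary()] in distribution
#' for small daily probabilities.
#'
#' @inheritParams simulate_unitary
#' @return The evolved [tract_population()].
#' @export
simulate_unitary_poisson <- function(pop, params, days, seed = NULL) {
  stopifnot(inherits(pop, "tract_population"),
            inherits(params, "drift_params"))
  if (days < 0) stop("days must be non-negative")
  with_seed(seed, {
    up <- stats::rpois(pop$n_tracts, params$p_e * days)
    dn <- stats::rpois(pop$n_tracts, params$p_c * days)
  })
  tract_population(pmax(pop$repeats + up - dn, 0L), pop$n_tracts,
                   pop$event_counts)
}

#' Peak-resolvability of a decomposition
#'
#' Fraction of adjacent fitted peak pairs whose separation exceeds twice the
#' pooled (area-weighted root-mean-square) component sigma. Near 1 for a
#' cleanly periodic population; collapses when unitary broadening merges the
#' periodic peaks.
#'
#' @param decomposition A `"peak_decomposition"` with at least 2 peaks.
#' @return A fraction in `[0, 1]`, or `NA` for a single-peak decomposition.
#' @export
peak_resolvability <- function(decomposition) {
  stopifnot(inherits(decomposition, "peak_decomposition"))
  pk <- decomposition$peaks[order(decomposition$peaks$mean_bp), ,
                            drop = FALSE]
  if (nrow(pk) < 2L) return(NA_real_)
  pooled <- sqrt(sum(pk$area * pk$sigma_bp^2) / sum(pk$area))
  mean(diff(pk$mean_bp) > 2 * pooled)
}

#' Write a population snapshot as delimited text
#'
#' Columns `tract_id`, `repeats`, `event_count`, preceded by `#`-prefixed
#' key-value header lines echoing the simulation configuration.
#'
#' @param pop A [tract_population()].
#' @param path Output file path.
#' @param config Optional named list echoed into the header.
#' @return `path`, invisibly.
#' @export
write_population <- function(pop, path, config = list()) {
  stopifnot(inherits(pop, "tract_population"))
  con <- file(path, "w")
  on.exit(close(con))
  for (k in names(config))
    writeLines(sprintf("# %s\t%s", k, format(config[[k]])), con)
  writeLines("tract_id\trepeats\tevent_count", con)
  utils::write.table(
    data.frame(tract_id = seq_len(pop$n_tracts), repeats = pop$repeats,
               event_count = pop$event_counts),
    con, sep = "\t", row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a population snapshot written by [write_population()]
#'
#' @param path Path to the snapshot.
#' @return A [tract_population()].
#' @export
read_population <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          comment.char = "#")
  tract_population(df$repeats, nrow(df), df$event_count)
}
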