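#' Unitary expansion/contraction parameters
#'
#' Per-tract per-day probabilities of a unitary (+1 repeat) expansion and a
#' (-1 repeat) contraction. Events are mutually exclusive within a day: on
#' any given day a tract expands with probability `p_e`, contracts with
#' probability `p_c`, and is otherwise unchanged.
#'
#' @param p_e Expansion probability per tract per day.
#' @param p_c Contraction probability per tract per day.
#' @return An object of class `"drift_params"`.
#' @examples
#' drift_params(0.026, 0.010)
#' @export
drift_params <- function(p_e, p_c) {
  if (p_e < 0 || p_c < 0) stop("probabilities must be non-negative")
  if (p_e + p_c > 1) stop("p_e + p_c must not exceed 1")
  structure(list(p_e = p_e, p_c = p_c), class = "drift_params")
}

#' @export
print.drift_params <- function(x, ...) {
  cat(sprintf(
    "<drift_params> p_e = %.4g, p_c = %.4g (total %.4g events/tract/day)\n",
    x$p_e, x$p_c, x$p_e + x$p_c))
  invisible(x)
}

#' Forward drift prediction for the unitary random walk
#'
#' Mean and standard deviation of the repeat-length distribution after a
#' given number of days of the daily +/-1 Bernoulli walk:
#' \deqn{\mu(t) = \mu_0 + (p_e - p_c) t}
#' \deqn{\sigma(t) = \sqrt{\sigma_0^2 + (p_e + p_c) t}}
#' The variance form drops the second-order term \eqn{(p_e - p_c)^2} of the
#' exact per-step variance \eqn{(p_e + p_c) - (p_e - p_c)^2}; see
#' [exact_step_variance()].
#'
#' @param params A [drift_params()].
#' @param mu0 Starting mean repeat count.
#' @param sigma0 Starting standard deviation, repeats (> 0).
#' @param days Elapsed time, days (>= 0).
#' @return A list with elements `mu` and `sigma` (repeats).
#' @examples
#' predict_drift(drift_params(0.026, 0.010), 119, 1.98, 119)
#' @export
predict_drift <- function(params, mu0, sigma0, days) {
  stopifnot(inherits(params, "drift_params"))
  if (days < 0) stop("days must be non-negative")
  list(mu = mu0 + (params$p_e - params$p_c) * days,
       sigma = sqrt(sigma0^2 + (params$p_e + params$p_c) * days))
}

#' @export
predict.drift_params <- function(object, mu0, sigma0, days, ...) {
  predict_drift(object, mu0, sigma0, days)
}

#' Exact per-step variance of the unitary walk
#'
#' The daily step takes values +1, -1, 0 with probabilities `p_e`, `p_c`,
#' `1 - p_e - p_c`, so its variance is
#' \eqn{(p_e + p_c) - (p_e - p_c)^2} per day. The drift equations use the
#' first term only; this helper exposes the neglected gap for documentation
#' and testing.
#'
#' @param params A [drift_params()].
#' @return Exact variance of one daily step, repeats^2.
#' @export
exact_step_variance <- function(params) {
  (params$p_e + params$p_c) - (params$p_e - params$p_c)^2
}

#' A paired mean/variance observation of one sample over time
#'
#' @param mu_start,mu_end Fitted mean repeat counts at the two time points.
#' @param sigma_start,sigma_end Fitted standard deviations (repeats, > 0).
#' @param elapsed_days Time between the observations, days (> 0).
#' @return An object of class `"drift_observation"`.
#' @export
drift_observation <- function(mu_start, mu_end, sigma_start, sigma_end,
                              elapsed_days) {
  if (sigma_start <= 0 || sigma_end <= 0) stop("sigmas must be positive")
  if (elapsed_days <= 0) stop("elapsed_days must be positive")
  structure(list(mu_start = mu_start, mu_end = mu_end,
                 sigma_start = sigma_start, sigma_end = sigma_end,
                 elapsed_days = elapsed_days),
            class = "drift_observation")
}

#' Invert the drift equations for the unitary probabilities
#'
#' Solves the forward moment equations for `p_e` and `p_c` given the change
#' in mean and standard deviation over an elapsed time:
#' \deqn{p_e = \frac{1}{2}\left(\frac{\Delta\sigma^2}{T} +
#'   \frac{\Delta\mu}{T}\right), \qquad
#'   p_c = \frac{1}{2}\left(\frac{\Delta\sigma^2}{T} -
#'   \frac{\Delta\mu}{T}\right)}
#' with \eqn{\Delta\sigma^2 = \sigma_{end}^2 - \sigma_{start}^2},
#' \eqn{\Delta\mu = \mu_{end} - \mu_{start}} and \eqn{T} in days. This is
#' the exact algebraic inverse of [predict_drift()].
#'
#' For the tail reference comparison (median expansion 1.97 repeats, sigma
#' 1.98 to 2.87 repeats) the default elapsed time is 119 days; see the
#' methods vignette for the 119- vs 126-day reading.
#'
#' @param obs A [drift_observation()], or `NULL` to pass the four moments
#'   directly.
#' @param mu_start,mu_end,sigma_start,sigma_end,elapsed_days Used when `obs`
#'   is `NULL`.
#' @return A [drift_params()].
#' @examples
#' estimate_drift(mu_start = 119, mu_end = 120.97,
#'                sigma_start = 1.98, sigma_end = 2.87, elapsed_days = 119)
#' @export
estimate_drift <- function(obs = NULL, mu_start, mu_end, sigma_start,
                           sigma_end, elapsed_days = 119) {
  if (is.null(obs))
    obs <- drift_observation(mu_start, mu_end, sigma_start, sigma_end,
                             elapsed_days)
  stopifnot(inherits(obs, "drift_observation"))
  dmu <- (obs$mu_end - obs$mu_start) / obs$elapsed_days
  dvar <- (obs$sigma_end^2 - obs$sigma_start^2) / obs$elapsed_days
  p_e <- (dvar + dmu) / 2
  p_c <- (dvar - dmu) / 2
  if (p_c < 0 || p_e < 0)
    stop(errorCondition(
      sprintf(paste0("variance change too small for the observed drift: ",
                     "raw p_e = %.5g, p_c = %.5g"), p_e, p_c),
      class = c("cagdyn_estimation_error", "error", "condition"),
      p_e = p_e, p_c = p_c))
  drift_params(p_e, p_c)
}

#' Scale a per-tract event rate to a genome-wide per-cell rate
#'
#' Extrapolates a per-tract per-day event rate measured on a repeat tract of
#' `tract_nt` nucleotides to the whole genome:
#' `rate * genome_nt / tract_nt` events per cell per day.
#'
#' @param per_tract_rate Events per tract per day.
#' @param tract_nt Tract length, nucleotides (default 360, a ~120-repeat CAG
#'   tract).
#' @param genome_nt Genome size, nucleotides (default 2.5e9, mouse).
#' @return Events per cell per day.
#' @examples
#' genomewide_rate(0.036)  # 250,000
#' @export
genomewide_rate <- function(per_tract_rate, tract_nt = 360,
                            genome_nt = 2.5e9) {
  if (tract_nt <= 0) stop("tract_nt must be positive")
  if (genome_nt <= 0) stop("genome_nt must be positive")
  if (per_tract_rate < 0) stop("rate must be non-negative")
  per_tract_rate * genome_nt / tract_nt
}

#' Summarise a cohort of drift observations
#'
#' Computes per-mouse expansions (delta mu), their median, histograms of the
#' fitted means and standard deviations by time point, and the per-time-point
#' ordinary least-squares trend of sigma on mu (the PCR-broadening trend
#' line). The trend can optionally be restricted to mice whose fitted mean
#' lies in the middle two quartiles, which removes leverage from extreme
#' founder lengths.
#'
#' @param per_mouse A list of [drift_observation()]s (optionally named by
#'   mouse).
#' @param middle_quartiles If `TRUE`, fit the sigma-on-mu trend only on
#'   observations with mu inside the interquartile range.
#' @return An object of class `"drift_cohort_summary"`: a list with
#'   `per_mouse` (data frame with `mouse`, `delta_mu`, start/end moments),
#'   `median_delta_mu`, `hist_mu`, `hist_sigma` (histograms by time point)
#'   and `trend` (per-time-point slope, intercept and n; slope is `NA` with
#'   a warning when the regressor is degenerate).
#' @export
cohort_summary <- function(per_mouse, middle_quartiles = FALSE) {
  if (!length(per_mouse)) stop("empty cohort")
  if (inherits(per_mouse, "drift_observation")) per_mouse <- list(per_mouse)
  stopifnot(all(vapply(per_mouse, inherits, logical(1), "drift_observation")))
  ids <- names(per_mouse)
  if (is.null(ids)) ids <- sprintf("mouse%03d", seq_along(per_mouse))
  df <- data.frame(
    mouse = ids,
    mu_start = vapply(per_mouse, `[[`, numeric(1), "mu_start"),
    mu_end = vapply(per_mouse, `[[`, numeric(1), "mu_end"),
    sigma_start = vapply(per_mouse, `[[`, numeric(1), "sigma_start"),
    sigma_end = vapply(per_mouse, `[[`, numeric(1), "sigma_end"),
    elapsed_days = vapply(per_mouse, `[[`, numeric(1), "elapsed_days"))
  df$delta_mu <- df$mu_end - df$mu_start

  fit_trend <- function(mu, sigma) {
    keep <- rep(TRUE, length(mu))
    if (middle_quartiles) {
      q <- stats::quantile(mu, c(0.25, 0.75))
      keep <- mu >= q[[1L]] & mu <= q[[2L]]
    }
    mu <- mu[keep]; sigma <- sigma[keep]
    if (length(unique(mu)) < 2L) {
      warning("degenerate regressor: sigma-on-mu slope undefined")
      return(c(slope = NA_real_, intercept = NA_real_, n = length(mu)))
    }
    fit <- stats::lm(sigma ~ mu)
    c(slope = unname(stats::coef(fit)[[2L]]),
      intercept = unname(stats::coef(fit)[[1L]]), n = length(mu))
  }
  trend <- rbind(start = fit_trend(df$mu_start, df$sigma_start),
                 end = fit_trend(df$mu_end, df$sigma_end))

  structure(list(
    per_mouse = df,
    median_delta_mu = stats::median(df$delta_mu),
    hist_mu = list(start = graphics::hist(df$mu_start, plot = FALSE),
                   end = graphics::hist(df$mu_end, plot = FALSE)),
    hist_sigma = list(start = graphics::hist(df$sigma_start, plot = FALSE),
                      end = graphics::hist(df$sigma_end, plot = FALSE)),
    trend = as.data.frame(trend),
    middle_quartiles = middle_quartiles),
    class = "drift_cohort_summary")
}

#' @export
print.drift_cohort_summary <- function(x, ...) {
  cat(sprintf("<drift_cohort_summary> %d mice, median expansion %.3f repeats\n",
              nrow(x$per_mouse), x$median_delta_mu))
  cat("sigma-on-mu trend (per time point):\n")
  print(round(x$trend, 4))
  invisible(x)
}

#' Write a cohort summary as delimited text plus a key-value stats file
#'
#' @param x A `"drift_cohort_summary"`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort_summary <- function(x, dir) {
  stopifnot(inherits(x, "drift_cohort_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(x$per_mouse, file.path(dir, "per_mouse.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  stats <- list(
    n_mice = nrow(x$per_mouse),
    median_delta_mu = x$median_delta_mu,
    mean_sigma_start = mean(x$per_mouse$sigma_start),
    mean_sigma_end = mean(x$per_mouse$sigma_end),
    trend_slope_start = x$trend["start", "slope"],
    trend_slope_end = x$trend["end", "slope"])
  write_keyvalue(stats, file.path(dir, "cohort_stats.txt"))
  invisible(dir)
}
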