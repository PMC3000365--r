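#' Consecutive peak-to-peak intervals in repeat units
#'
#' Differences between consecutive fitted peak means, converted from bp to
#' CAG repeats (divided by 3). A decomposition with fewer than two peaks
#' contributes an empty interval set rather than an error.
#'
#' @param decomposition A `"peak_decomposition"`.
#' @param sample_id Optional identifier attached to each interval.
#' @return An object of class `"interval_set"`: list with numeric
#'   `intervals` (repeats) and character `sample` of the same length.
#' @export
peak_intervals <- function(decomposition, sample_id = NA_character_) {
  stopifnot(inherits(decomposition, "peak_decomposition"))
  mu <- sort(decomposition$peaks$mean_bp)
  ints <- if (length(mu) < 2L) numeric(0) else diff(mu) / BP_PER_REPEAT
  interval_set(ints, rep(as.character(sample_id), length(ints)))
}

#' @rdname peak_intervals
#' @param intervals Positive separations in repeats.
#' @param sample Sample identifiers, recycled to `length(intervals)`.
#' @export
interval_set <- function(intervals = numeric(0), sample = character(0)) {
  intervals <- as.numeric(intervals)
  if (length(intervals) && any(intervals <= 0))
    stop("intervals must be positive")
  sample <- rep_len(as.character(sample),
                    if (length(intervals)) length(intervals) else 0L)
  structure(list(intervals = intervals, sample = sample),
            class = "interval_set")
}

#' Pool interval sets from many samples
#'
#' @param ... `"interval_set"` objects, or a single list of them.
#' @return The pooled `"interval_set"`.
#' @export
pool_intervals <- function(...) {
  sets <- list(...)
  if (length(sets) == 1L && !inherits(sets[[1L]], "interval_set"))
    sets <- sets[[1L]]
  stopifnot(all(vapply(sets, inherits, logical(1), "interval_set")))
  interval_set(unlist(lapply(sets, `[[`, "intervals")),
               unlist(lapply(sets, `[[`, "sample")))
}

#' @export
print.interval_set <- function(x, ...) {
  cat(sprintf("<interval_set> %d interval(s) from %d sample(s)\n",
              length(x$intervals), length(unique(x$sample))))
  invisible(x)
}

#' Interval statistics with the doublet cutoff
#'
#' Intervals at or above `doublet_cutoff` repeats are treated as doublets --
#' two consecutive insertion steps whose intermediate peak went unresolved --
#' and are excluded from the statistics. With `halve_doublets = TRUE` each
#' excluded interval is instead replaced by two intervals of half its size.
#'
#' @param pooled An `"interval_set"` (typically pooled across samples).
#' @param doublet_cutoff Exclusion threshold in repeats (default 12).
#' @param halve_doublets Re-admit excluded intervals as two half-steps.
#' @return A list with `mean`, `median`, `sd` (repeats), `n_used` and
#'   `n_excluded`.
#' @examples
#' interval_stats(interval_set(c(7, 7, 14)))
#' @export
interval_stats <- function(pooled, doublet_cutoff = 12,
                           halve_doublets = FALSE) {
  stopifnot(inherits(pooled, "interval_set"))
  v <- pooled$intervals
  excl <- v >= doublet_cutoff
  used <- v[!excl]
  if (halve_doublets) used <- c(used, rep(v[excl] / 2, each = 2L))
  if (!length(used))
    stop(errorCondition("no intervals remain below the doublet cutoff",
                        class = c("cagdyn_estimation_error", "error",
                                  "condition")))
  list(mean = mean(used), median = stats::median(used),
       sd = stats::sd(used), n_used = length(used),
       n_excluded = sum(excl))
}

#' Interval histogram with integer bins
#'
#' Counts of intervals rounded to the nearest integer repeat, optionally
#' split by an age grouping, as delimited-text-ready data.
#'
#' @param pooled An `"interval_set"`.
#' @param age_weeks Optional numeric vector parallel to the intervals giving
#'   the source sample's age; when given, per-age-group count columns are
#'   added.
#' @return A data frame with `interval_repeats` (integer bin) and `count`
#'   (plus one column per age group).
#' @export
interval_histogram <- function(pooled, age_weeks = NULL) {
  stopifnot(inherits(pooled, "interval_set"))
  r <- round(pooled$intervals)
  bins <- if (length(r)) seq(min(r), max(r)) else integer(0)
  out <- data.frame(interval_repeats = bins,
                    count = as.integer(table(factor(r, levels = bins))))
  if (!is.null(age_weeks)) {
    for (a in sort(unique(age_weeks))) {
      cnt <- table(factor(r[age_weeks == a], levels = bins))
      out[[sprintf("count_%gwk", a)]] <- as.integer(cnt)
    }
  }
  out
}

#' Per-peak tract counts rescaled to a fixed sample size
#'
#' Fitted peak areas are proportional to the number of tracts at each length
#' class, so rescaling the areas to the approximate number of cells in a
#' sample (10,000 by default) converts them into tract counts. The insertion
#' index k is assigned ordinally: the first (lowest-mean) peak is the
#' founder class k = 0, the next k = 1, and so on. When consecutive peak
#' spacings deviate from the modal spacing by more than 50\% a consistency
#' warning is raised, and `mode = "spacing"` instead assigns
#' `k = round((mu_k - mu_0) / (3 * modal_step))`.
#'
#' @param decomposition A `"peak_decomposition"`.
#' @param total_tracts Total tract count the areas are rescaled to.
#' @param mode `"ordinal"` (default) or `"spacing"` k-assignment.
#' @return An object of class `"area_proportions"`: list with `counts`
#'   (named by k), `k` (integer insertion indices), `total_tracts` and
#'   `modal_step_repeats`.
#' @export
area_proportions <- function(decomposition, total_tracts = 10000,
                             mode = c("ordinal", "spacing")) {
  stopifnot(inherits(decomposition, "peak_decomposition"))
  mode <- match.arg(mode)
  pk <- decomposition$peaks[order(decomposition$peaks$mean_bp), ,
                            drop = FALSE]
  counts <- total_tracts * pk$area / sum(pk$area)
  n <- nrow(pk)
  modal_step <- NA_real_
  k <- seq_len(n) - 1L
  if (n >= 2L) {
    steps <- diff(pk$mean_bp) / BP_PER_REPEAT
    # unit ladder step: a skipped class shows up as a near-multiple of the
    # smallest step, so reduce each spacing by its multiplicity first
    mult <- pmax(round(steps / min(steps)), 1)
    modal_step <- stats::median(steps / mult)
    if (any(abs(steps - modal_step) > 0.5 * modal_step))
      warning("inconsistent peak spacing: ordinal insertion index may ",
              "miscount skipped classes")
    if (mode == "spacing")
      k <- as.integer(round((pk$mean_bp - pk$mean_bp[[1L]]) /
                              (BP_PER_REPEAT * modal_step)))
  }
  structure(list(counts = stats::setNames(counts, k), k = k,
                 total_tracts = total_tracts,
                 modal_step_repeats = modal_step),
            class = "area_proportions")
}

#' @export
print.area_proportions <- function(x, ...) {
  cat(sprintf("<area_proportions> %d class(es), %g tracts\n",
              length(x$counts), x$total_tracts))
  print(round(x$counts, 1))
  invisible(x)
}

#' Fraction of tracts retaining the founder length
#'
#' The first fitted peak's share of the rescaled tract counts: the
#' proportion of the sample that has undergone no insertion event.
#'
#' @param props An [area_proportions()].
#' @return A fraction in `[0, 1]`.
#' @export
nonexpanding_fraction <- function(props) {
  stopifnot(inherits(props, "area_proportions"))
  unname(props$counts[props$k == 0L] / props$total_tracts)
}

#' Total number of insertion events implied by the peak areas
#'
#' Each tract in class k has undergone k insertion events, so the sample
#' total is the sum of k times the rescaled class counts.
#'
#' @param props An [area_proportions()].
#' @return Estimated number of insertion events in the sample.
#' @export
total_insertions <- function(props) {
  stopifnot(inherits(props, "area_proportions"))
  sum(props$k * props$counts)
}

#' Periodic insertion event rate
#'
#' Events per tract per day, with the tract denominator taken either as the
#' expanding subpopulation (total minus the founder class; default) or as
#' all tracts. Both conventions are legitimate summaries and both are
#' reported by the cohort analysis.
#'
#' @param insertions Number of insertion events (e.g. [total_insertions()]).
#' @param props The [area_proportions()] supplying the denominators.
#' @param days Elapsed time, days (> 0).
#' @param denominator `"expanding_tracts"` (default) or `"all_tracts"`.
#' @return Events per tract per day.
#' @examples
#' # 10,000 insertions over 4,500 expanding tracts in 126 days ~ 0.018
#' @export
periodic_event_rate <- function(insertions, props, days,
                                denominator = c("expanding_tracts",
                                                "all_tracts")) {
  stopifnot(inherits(props, "area_proportions"))
  denominator <- match.arg(denominator)
  if (days <= 0) stop("days must be positive")
  n0 <- sum(props$counts[props$k == 0L])
  n <- switch(denominator,
              expanding_tracts = props$total_tracts - n0,
              all_tracts = props$total_tracts)
  if (n <= 0)
    stop(errorCondition("no expanding tracts in denominator",
                        class = c("cagdyn_estimation_error", "error",
                                  "condition")))
  insertions / (n * days)
}
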